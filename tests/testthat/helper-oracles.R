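# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity by the most naive route
# (enumeration, per-base scans) and never call the implementation path
# they check.

# exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# assignments (midranks, zeros dropped)
oracleSignedRankP <- function(x) {
  x <- x[!is.na(x) & x != 0]
  n <- length(x)
  if (n == 0L) return(1)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  mu <- sum(r) / 2
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    wk <- sum(r[signs])
    if (abs(wk - mu) >= abs(w - mu) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

# per-base strand-aware overlap counting: returns feature counts for one
# sample following the assignment rules (>=1 base same-strand overlap,
# multi-gene reads discarded, within-gene ties to larger overlap then 3')
oracleCountReads <- function(features, reads) {
  fids <- unique(features$feature_id)
  out <- stats::setNames(rep(0L, length(fids)), fids)
  featBase <- lapply(fids, function(f) {
    sub <- features[features$feature_id == f]
    list(chrom = as.character(GenomicRanges::seqnames(sub))[1],
         strand = as.character(GenomicRanges::strand(sub))[1],
         bases = unlist(mapply(seq, GenomicRanges::start(sub),
                               GenomicRanges::end(sub),
                               SIMPLIFY = FALSE)),
         gene = sub$gene_id[1],
         pos3 = if (as.character(GenomicRanges::strand(sub))[1] == "+")
           max(GenomicRanges::end(sub)) else -min(GenomicRanges::start(sub)))
  })
  names(featBase) <- fids
  for (i in seq_along(reads)) {
    rb <- seq(GenomicRanges::start(reads)[i], GenomicRanges::end(reads)[i])
    rc <- as.character(GenomicRanges::seqnames(reads))[i]
    rs <- as.character(GenomicRanges::strand(reads))[i]
    ovs <- vapply(featBase, function(fb) {
      if (fb$chrom != rc || fb$strand != rs) 0L
      else length(intersect(rb, fb$bases))
    }, integer(1))
    hit <- which(ovs > 0L)
    if (length(hit) == 0L) next
    genes <- unique(vapply(featBase[hit], `[[`, "", "gene"))
    if (length(genes) > 1L) next
    pos3 <- vapply(featBase[hit], `[[`, numeric(1), "pos3")
    best <- hit[order(-ovs[hit], -pos3)][1]
    out[best] <- out[best] + 1L
  }
  out
}

# does the sequence contain a G-quadruplex match of
# ([gG]{3,}\w{1,7}){3,}[gG]{3,}? Exact existence check by reachability DP
# over the pattern grammar: A[k][j] is true when k repetitions of
# "G-run(>=3) + loop(1..7 of anything)" can end exactly at position j
# (k saturates at 3 for the {3,} quantifier); a match exists when some
# A[>=3][j] is followed by >= 3 Gs
oracleHasG4 <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n < 15L) return(FALSE)
  isG <- ch == "G"
  runEnd <- integer(n)                  # G-run length ending at position
  for (i in seq_len(n)) {
    runEnd[i] <- if (isG[i]) (if (i > 1L) runEnd[i - 1L] else 0L) + 1L
                 else 0L
  }
  A <- matrix(FALSE, nrow = 3L, ncol = n)  # A[k, j]; k saturated at 3
  for (j in seq_len(n)) {
    for (l in 1:7) {                    # loop of length l ends at j
      pos <- j - l                      # G-run ends at pos
      if (pos < 3L) next
      if (runEnd[pos] < 3L) next
      for (g in 3:runEnd[pos]) {
        before <- pos - g               # repetitions ending before the run
        A[1L, j] <- TRUE
        if (before >= 1L) {
          if (A[1L, before]) A[2L, j] <- TRUE
          if (A[2L, before]) A[3L, j] <- TRUE
          if (A[3L, before]) A[3L, j] <- TRUE
        }
      }
    }
  }
  for (j in which(A[3L, ])) {
    if (j + 3L <= n && all(isG[(j + 1L):(j + 3L)])) return(TRUE)
  }
  FALSE
}

# naive per-window PWM log-odds scores
oraclePwmScores <- function(seq, mat, background = rep(0.25, 4)) {
  seq <- toupper(chartr("Tt", "Uu", seq))
  b <- strsplit(seq, "")[[1]]
  w <- nrow(mat)
  L <- length(b)
  if (L < w) return(numeric(0))
  vapply(seq_len(L - w + 1L), function(i) {
    s <- 0
    for (j in seq_len(w)) {
      x <- match(b[i + j - 1L], c("A", "C", "G", "U"))
      if (!is.na(x)) s <- s + log2(mat[j, x] / background[x])
    }
    s
  }, numeric(1))
}

# exhaustive alignment enumeration for tiny covariance models: mirrors the
# grammar (CORE = emit/delete; affine insert runs feed CORE) by direct
# recursion over spans
oracleCmScore <- function(model, seq) {
  seq <- toupper(chartr("Tt", "Uu", seq))
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  go <- model@gapOpen; ge <- model@gapExtend
  insRun <- function(len) if (len <= 0) 0 else -(go + (len - 1) * ge)
  pairS <- function(v, x, y) {
    if (is.na(x) || is.na(y)) 0 else model@pairEmit[v, 4 * (x - 1) + y]
  }
  singleS <- function(v, x) if (is.na(x)) 0 else model@singleEmit[v, x]
  M <- function(v, i, j) {
    ty <- model@nodeType[v]
    if (ty == 4L) return(if (j < i) 0 else insRun(j - i + 1))
    if (ty == 3L) {
      best <- -Inf
      for (k in (i - 1):j)
        best <- max(best, M(model@child1[v], i, k) +
                      M(model@child2[v], k + 1, j))
      return(best)
    }
    best <- CORE(v, i, j)
    len <- j - i + 1
    if (len >= 1) {
      for (t in seq_len(len)) {
        best <- max(best, insRun(t) + CORE(v, i + t, j))   # left inserts
        best <- max(best, insRun(t) + CORE(v, i, j - t))   # right inserts
      }
    }
    best
  }
  CORE <- function(v, i, j) {
    ty <- model@nodeType[v]
    c1 <- model@child1[v]
    best <- M(c1, i, j) - model@delCost[v]
    if (ty == 0L && j - i + 1 >= 2)
      best <- max(best, pairS(v, b[i], b[j]) + M(c1, i + 1, j - 1))
    if (ty == 1L && j >= i)
      best <- max(best, singleS(v, b[i]) + M(c1, i + 1, j))
    if (ty == 2L && j >= i)
      best <- max(best, singleS(v, b[j]) + M(c1, i, j - 1))
    best
  }
  root <- length(model@nodeType)
  best <- -Inf
  L <- length(b)
  for (i in 1:(L + 1))
    for (j in (i - 1):L)
      best <- max(best, M(root, i, j))
  best
}

# small random nucleotide sequence
randomSeq <- function(L, comp = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(comp), L, replace = TRUE, prob = comp), collapse = "")
}
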