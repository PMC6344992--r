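#' Find potential G-quadruplex-forming regions
#'
#' Scans a nucleotide sequence for runs matching the canonical
#' G-quadruplex pattern: four runs of three or more guanines separated by
#' loops of 1-7 arbitrary nucleotides, i.e. the regular expression
#' \code{([gG]\{3,\}\\w\{1,7\})\{3,\}[gG]\{3,\}}. Matching is the standard
#' greedy, non-overlapping, left-to-right regex semantics.
#'
#' @param seq a single nucleotide string (DNA or RNA alphabet, any case) or
#'   an object coercible with \code{as.character}.
#' @return data.frame of hits: start, end (1-based inclusive), match. Zero
#'   rows when no match.
#' @export
findGQuadruplex <- function(seq) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  m <- gregexpr("([gG]{3,}\\w{1,7}){3,}[gG]{3,}", seq, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0)))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             match = substring(seq, m, m + len - 1L))
}

## ---------------------------------------------------------------------------

#' Pwm: position weight matrix with a per-motif log-odds threshold
#'
#' Column-probability matrix over A/C/G/U with a background distribution
#' and a hit threshold in bits. \code{nInformative} counts the positions
#' whose information content reaches the cutoff used to set the threshold.
#'
#' @slot motifId motif label.
#' @slot mat positions x 4 probability matrix (columns A, C, G, U; rows sum
#'   to 1).
#' @slot background length-4 background probabilities.
#' @slot threshold log-odds hit threshold in bits.
#' @slot nInformative number of informative positions.
#' @export
setClass("Pwm",
  representation(motifId = "character", mat = "matrix",
                 background = "numeric", threshold = "numeric",
                 nInformative = "integer"))

setValidity("Pwm", function(object) {
  msg <- character()
  if (ncol(object@mat) != 4L) msg <- c(msg, "matrix must have 4 columns")
  if (any(abs(rowSums(object@mat) - 1) > 1e-6))
    msg <- c(msg, "matrix rows must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Pwm", function(object) {
  cat("Pwm", object@motifId, ":", nrow(object@mat), "positions,",
      object@nInformative, "informative, threshold",
      round(object@threshold, 2), "bits\n")
})

#' Construct a Pwm and set its per-motif threshold
#'
#' The hit threshold scales with motif specificity: it is \code{c} bits per
#' informative position, where a position is informative when its
#' information content (relative entropy to the background, in bits) is at
#' least \code{icCut}. Longer, more specific motifs therefore need a higher
#' log-odds score to call a match.
#'
#' @param mat positions x 4 probability matrix (columns A, C, G, U/T).
#' @param motifId motif label.
#' @param background background base probabilities (default uniform).
#' @param c bits of threshold per informative position (default 1).
#' @param icCut information content cutoff in bits (default 0.5).
#' @return a \code{Pwm}.
#' @export
pwm <- function(mat, motifId = "pwm", background = rep(0.25, 4), c = 1.0,
                icCut = 0.5) {
  mat <- as.matrix(mat)
  colnames(mat) <- c("A", "C", "G", "U")
  nInf <- pwmInformativePositions(mat, background, icCut)
  methods::new("Pwm", motifId = motifId, mat = mat,
               background = background, threshold = c * nInf,
               nInformative = nInf)
}

#' Count informative PWM positions
#'
#' @param mat positions x 4 probability matrix.
#' @param background background probabilities.
#' @param icCut information content cutoff in bits.
#' @return integer count of positions with IC >= icCut.
#' @export
pwmInformativePositions <- function(mat, background = rep(0.25, 4),
                                    icCut = 0.5) {
  ic <- apply(mat, 1, function(p) {
    sum(ifelse(p > 0, p * log2(p / background), 0))
  })
  sum(ic >= icCut)
}

#' Read a CISBP-RNA-style PWM file
#'
#' Tab-delimited file with a position column followed by per-base
#' probability columns (A, C, G, U).
#'
#' @param path file path.
#' @param motifId motif label (default: file base name).
#' @param ... passed to \code{\link{pwm}} (threshold parameters).
#' @return a \code{Pwm}.
#' @export
readCisbpPwm <- function(path, motifId = NULL, ...) {
  tab <- utils::read.delim(path, check.names = FALSE)
  baseCols <- intersect(c("A", "C", "G", "U", "T"), colnames(tab))
  stopifnot(length(baseCols) == 4L)
  mat <- as.matrix(tab[, baseCols])
  if (is.null(motifId))
    motifId <- tools::file_path_sans_ext(basename(path))
  pwm(mat, motifId = motifId, ...)
}

#' Scan a sequence with a PWM
#'
#' Slides the motif along the sequence and scores every window by the
#' log-odds sum \eqn{\sum_j \log_2(p_{j,b_j} / q_{b_j})} in bits. Positions
#' with an N contribute 0 (scored as background). T and U are equivalent.
#' Windows scoring at or above the motif threshold are reported.
#'
#' @param seq nucleotide string (or coercible).
#' @param pwmObj a \code{Pwm}.
#' @return data.frame of hits: start, end, score (all windows meeting the
#'   threshold).
#' @export
scanPwm <- function(seq, pwmObj) {
  stopifnot(methods::is(pwmObj, "Pwm"))
  scores <- pwmScores(seq, pwmObj)
  w <- nrow(pwmObj@mat)
  hit <- which(scores >= pwmObj@threshold)
  data.frame(start = hit, end = hit + w - 1L, score = scores[hit])
}

#' All sliding-window PWM log-odds scores
#'
#' @param seq nucleotide string.
#' @param pwmObj a \code{Pwm}.
#' @return numeric vector of window scores (length L - width + 1; length 0
#'   when the sequence is shorter than the motif).
#' @export
pwmScores <- function(seq, pwmObj) {
  seq <- toupper(chartr("Tt", "Uu", as.character(seq)))
  w <- nrow(pwmObj@mat)
  L <- nchar(seq)
  if (L < w) return(numeric(0))
  baseIdx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  lo <- log2(sweep(pwmObj@mat, 2, pwmObj@background, "/"))
  nWin <- L - w + 1L
  scores <- numeric(nWin)
  for (j in seq_len(w)) {
    b <- baseIdx[j:(j + nWin - 1L)]
    contrib <- ifelse(is.na(b), 0, lo[j, ifelse(is.na(b), 1L, b)])
    scores <- scores + contrib
  }
  scores
}

#' Per-gene motif hit indicator over a sequence set
#'
#' Applies a scanner to each sequence and reports whether each gene has at
#' least one hit (the unit used by \code{\link{fisherEnrichment}}).
#'
#' @param seqs named character vector (or \code{DNAStringSet} /
#'   \code{RNAStringSet}) of 3'UTR sequences, one per gene.
#' @param scanner function(seq) returning a data.frame with one row per
#'   hit, e.g. \code{findGQuadruplex} or \code{function(s) scanPwm(s, p)}.
#' @return named logical vector: gene has >= 1 hit.
#' @export
genesWithHit <- function(seqs, scanner) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  vapply(seqs, function(s) nrow(scanner(s)) > 0L, logical(1))
}
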