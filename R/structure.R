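#' @useDynLib DendriteLoc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' StructureExemplar: a canonical sequence with its secondary structure
#'
#' A single exemplar (consensus sequence plus dot-bracket structure) from
#' which a covariance model is built, together with the bitscore cutoff
#' above which a scanned match is called high-quality.
#'
#' @slot name element name.
#' @slot sequence RNA sequence (U or T accepted).
#' @slot structure dot-bracket string of the same length, balanced and
#'   non-crossing.
#' @slot cutoff bitscore cutoff for high-quality matches.
#' @export
setClass("StructureExemplar",
  representation(name = "character", sequence = "character",
                 structure = "character", cutoff = "numeric"))

setValidity("StructureExemplar", function(object) {
  msg <- character()
  if (nchar(object@sequence) != nchar(object@structure))
    msg <- c(msg, "sequence and structure must have equal length")
  ok <- tryCatch({ .pairPartners(object@structure); TRUE },
                 error = function(e) FALSE)
  if (!ok) msg <- c(msg, "structure brackets must be balanced")
  if (length(msg)) msg else TRUE
})

#' @rdname StructureExemplar-class
#' @param name,sequence,structure,cutoff see slots
#' @export
structureExemplar <- function(name, sequence, structure, cutoff) {
  methods::new("StructureExemplar", name = name,
               sequence = toupper(chartr("Tt", "Uu", sequence)),
               structure = structure, cutoff = cutoff)
}

setMethod("show", "StructureExemplar", function(object) {
  cat("StructureExemplar", object@name, ":", nchar(object@sequence),
      "nt,", sum(strsplit(object@structure, "")[[1]] == "("), "base pairs,",
      "cutoff", object@cutoff, "bits\n")
})

#' Shipped B1 SINE exemplar
#'
#' Canonical murine B1 SINE consensus with its minimum-free-energy hairpin
#' structure; high-quality matches require 50 bits.
#' @return a \code{StructureExemplar}.
#' @export
b1Exemplar <- function() {
  structureExemplar("B1",
    paste0("GAGGCAGGCGGATTTCTGAGTTCGAGGCCAGCCTGGTCTACAGAGTGAGTTCCAGGACA",
           "GCCAGGGCTACACAGAGAAACCCTGTCTC"),
    paste0("((((((((....(((((((((((..(((...(((((.((........))..)))))...",
           "))).)))))...))))))...))))))))"),
    cutoff = 50)
}

#' Shipped B2 SINE exemplar
#'
#' Canonical murine B2 SINE consensus with its minimum-free-energy hairpin
#' structure; high-quality matches require 35 bits.
#' @return a \code{StructureExemplar}.
#' @export
b2Exemplar <- function() {
  structureExemplar("B2",
    "GCTGGTGAGATGGCTCAGTGGGTAAGAGCACCCGACTGCTCTTCCGAAGGTCAGGAGTTCAAATCCCAGC",
    "(((((.((..((((((....((.(((((((......))))))))).........))).)))..)))))))",
    cutoff = 35)
}

## pairing partner of each '(' / ')'; error on unbalanced or crossing input
.pairPartners <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("structure may contain only '(', ')' and '.'")
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure")
  partner
}

## ---------------------------------------------------------------------------

#' StructureModel: single-exemplar profile SCFG
#'
#' Guide tree derived from the exemplar's bracket nesting (one pair node
#' per base pair, one left/right node per unpaired base, bifurcations at
#' multiloop branch points) with pseudocount-smoothed log-odds emissions
#' centered on the exemplar bases and affine insertion costs; alignment is
#' global to the model with free end insertions at the root (glocal), so a
#' match may sit anywhere inside a scanned window.
#'
#' @slot name model name.
#' @slot nodeType integer per node: 0 pair, 1 left, 2 right, 3 bifurcation,
#'   4 end.
#' @slot child1,child2 integer child indices (1-based; NA where absent).
#' @slot pairEmit nodes x 16 pair emission log-odds (bits); row used for
#'   pair nodes only, column index 4*(x-1)+y over A,C,G,U.
#' @slot singleEmit nodes x 4 single emission log-odds (bits).
#' @slot delCost positive per-node deletion cost (bits).
#' @slot gapOpen,gapExtend affine insertion costs (bits).
#' @slot cutoff bitscore cutoff inherited from the exemplar.
#' @slot exemplarLength length of the exemplar sequence.
#' @export
setClass("StructureModel",
  representation(name = "character", nodeType = "integer",
                 child1 = "integer", child2 = "integer",
                 pairEmit = "matrix", singleEmit = "matrix",
                 delCost = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric", cutoff = "numeric",
                 exemplarLength = "integer"))

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel", object@name, ":", length(object@nodeType), "nodes (",
      sum(object@nodeType == 0L), "pair,",
      sum(object@nodeType %in% c(1L, 2L)), "single,",
      sum(object@nodeType == 3L), "bifurcation ), cutoff", object@cutoff,
      "bits\n")
})

#' Build a covariance model from a structure exemplar
#'
#' Emissions are log-odds (bits) against a uniform null: the probability
#' mass sits on the exemplar's base (or base pair) and is smoothed with
#' \code{pseudocount}; pair-node emissions additionally receive
#' \code{pairBonus} and lose \code{mismatchPenalty} when the emitted pair
#' differs from the exemplar's. Deleting a node costs \code{gapOpen}
#' (plus \code{gapExtend} for the second base of a pair node); inserting a
#' run of k bases costs \code{gapOpen + (k-1) gapExtend}.
#'
#' @param ex a \code{StructureExemplar}.
#' @param pairBonus bits added to every pair-node emission (default 0.5).
#' @param mismatchPenalty bits subtracted from non-exemplar pair emissions
#'   (default 1).
#' @param gapOpen gap opening cost in bits (default 4).
#' @param gapExtend gap extension cost in bits (default 1).
#' @param pseudocount emission smoothing mass (default 0.05).
#' @return a \code{StructureModel}.
#' @export
buildStructureModel <- function(ex, pairBonus = 0.5, mismatchPenalty = 1,
                                gapOpen = 4, gapExtend = 1,
                                pseudocount = 0.05) {
  stopifnot(methods::is(ex, "StructureExemplar"))
  methods::validObject(ex)
  partner <- .pairPartners(ex@structure)
  bases <- match(strsplit(ex@sequence, "")[[1]], c("A", "C", "G", "U"))
  if (anyNA(bases)) stop("exemplar sequence must be over A/C/G/U (or T)")

  nodes <- new.env()
  nodes$type <- integer(0); nodes$c1 <- integer(0); nodes$c2 <- integer(0)
  nodes$b1 <- integer(0); nodes$b2 <- integer(0)
  addNode <- function(type, c1 = NA_integer_, c2 = NA_integer_,
                      b1 = NA_integer_, b2 = NA_integer_) {
    nodes$type <- c(nodes$type, type)
    nodes$c1 <- c(nodes$c1, c1); nodes$c2 <- c(nodes$c2, c2)
    nodes$b1 <- c(nodes$b1, b1); nodes$b2 <- c(nodes$b2, b2)
    length(nodes$type)
  }
  ch <- strsplit(ex@structure, "")[[1]]
  parse <- function(i, j) {
    if (i > j) return(addNode(4L))
    if (ch[i] == ".") {
      c1 <- parse(i + 1L, j)
      return(addNode(1L, c1 = c1, b1 = bases[i]))
    }
    if (ch[j] == ".") {
      c1 <- parse(i, j - 1L)
      return(addNode(2L, c1 = c1, b1 = bases[j]))
    }
    k <- partner[i]
    if (k == j) {
      c1 <- parse(i + 1L, j - 1L)
      return(addNode(0L, c1 = c1, b1 = bases[i], b2 = bases[j]))
    }
    c1 <- parse(i, k)
    c2 <- parse(k + 1L, j)
    addNode(3L, c1 = c1, c2 = c2)
  }
  parse(1L, length(ch))

  nN <- length(nodes$type)
  pairEmit <- matrix(0, nN, 16)
  singleEmit <- matrix(0, nN, 4)
  delCost <- rep(gapOpen, nN)
  for (v in seq_len(nN)) {
    if (nodes$type[v] == 0L) {
      a <- nodes$b1[v]; b <- nodes$b2[v]
      p <- matrix(pseudocount, 4, 4)
      p[a, b] <- p[a, b] + 1
      p <- p / sum(p)
      sc <- log2(p * 16) + pairBonus
      sc <- sc - mismatchPenalty
      sc[a, b] <- sc[a, b] + mismatchPenalty
      pairEmit[v, ] <- as.numeric(t(sc))   # column index 4*(x-1)+y
      delCost[v] <- gapOpen + gapExtend
    } else if (nodes$type[v] %in% c(1L, 2L)) {
      a <- nodes$b1[v]
      p <- rep(pseudocount, 4)
      p[a] <- p[a] + 1
      p <- p / sum(p)
      singleEmit[v, ] <- log2(p * 4)
    }
  }
  methods::new("StructureModel", name = ex@name, nodeType = nodes$type,
               child1 = nodes$c1, child2 = nodes$c2, pairEmit = pairEmit,
               singleEmit = singleEmit, delCost = delCost,
               gapOpen = gapOpen, gapExtend = gapExtend,
               cutoff = ex@cutoff, exemplarLength = nchar(ex@sequence))
}

#' Score a sequence window against a covariance model
#'
#' Maximum-scoring (CYK-style inside-max) alignment of the window to the
#' model, in bits against the uniform null. End insertions at the root are
#' free, so the reported score is the best-scoring subsequence of the
#' window aligned globally to the model. Deterministic; invariant to case
#' and T/U; N bases score 0.
#'
#' @param model a \code{StructureModel}.
#' @param seq nucleotide string (or coercible).
#' @return bitscore (numeric scalar).
#' @export
scoreWindow <- function(model, seq) {
  stopifnot(methods::is(model, "StructureModel"))
  seq <- toupper(chartr("Tt", "Uu", as.character(seq)))
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  idx[is.na(idx)] <- 5L                  # N and friends
  cmScoreCpp(model@nodeType, model@child1, model@child2, model@pairEmit,
             model@singleEmit, model@delCost, model@gapOpen,
             model@gapExtend, as.integer(idx) - 1L)
}

#' Scan UTR sequences for structure-conserved matches
#'
#' Tiles each sequence into sliding windows, scores every window against
#' the model, and keeps the best window per gene (one match per gene). A
#' gene passes when its best bitscore reaches the model cutoff. Sequences
#' shorter than half the model length yield no windows and no hit.
#'
#' @param model a \code{StructureModel}.
#' @param seqs named character vector or \code{XStringSet} of 3'UTR
#'   sequences (one per gene).
#' @param window window width in nt (default 250).
#' @param slide window step in nt (default 75).
#' @return data.frame: gene_id, start, end, bitscore, passes.
#' @export
scanStructures <- function(model, seqs, window = 250L, slide = 75L) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  minLen <- ceiling(0.5 * model@exemplarLength)
  rows <- lapply(names(seqs), function(g) {
    s <- seqs[[g]]
    L <- nchar(s)
    if (L < minLen)
      return(data.frame(gene_id = g, start = NA_integer_,
                        end = NA_integer_, bitscore = -Inf,
                        passes = FALSE))
    starts <- unique(pmin(seq(1L, max(1L, L - window + 1L), by = slide),
                          max(1L, L - window + 1L)))
    best <- -Inf; bestStart <- NA_integer_; bestEnd <- NA_integer_
    for (st in starts) {
      en <- min(st + window - 1L, L)
      if (en - st + 1L < minLen) next
      sc <- scoreWindow(model, substr(s, st, en))
      if (sc > best) { best <- sc; bestStart <- st; bestEnd <- en }
    }
    data.frame(gene_id = g, start = bestStart, end = bestEnd,
               bitscore = best, passes = is.finite(best) &&
                 best >= model@cutoff)
  })
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------

#' Serialize / restore a StructureModel as JSON
#'
#' @param model a \code{StructureModel}.
#' @param path output file.
#' @return \code{writeStructureModel} returns \code{path} invisibly;
#'   \code{readStructureModel} returns the restored model.
#' @export
writeStructureModel <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite required for model serialization")
  obj <- list(name = model@name, nodeType = model@nodeType,
              child1 = model@child1, child2 = model@child2,
              pairEmit = model@pairEmit, singleEmit = model@singleEmit,
              delCost = model@delCost, gapOpen = model@gapOpen,
              gapExtend = model@gapExtend, cutoff = model@cutoff,
              exemplarLength = model@exemplarLength)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeStructureModel
#' @export
readStructureModel <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite required for model serialization")
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("StructureModel", name = o$name,
               nodeType = as.integer(o$nodeType),
               child1 = as.integer(o$child1), child2 = as.integer(o$child2),
               pairEmit = matrix(unlist(o$pairEmit),
                                 nrow = length(o$nodeType)),
               singleEmit = matrix(unlist(o$singleEmit),
                                   nrow = length(o$nodeType)),
               delCost = as.numeric(o$delCost), gapOpen = o$gapOpen,
               gapExtend = o$gapExtend, cutoff = o$cutoff,
               exemplarLength = as.integer(o$exemplarLength))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide counts
#' (Eulerian-walk shuffle with rejection), the standard null for structure
#' and motif scans.
#'
#' @param seq nucleotide string.
#' @param maxTries rejection-sampling cap (default 10000).
#' @return shuffled string with identical dinucleotide composition.
#' @export
dinucleotideShuffle <- function(seq, maxTries = 10000L) {
  ch <- strsplit(as.character(seq), "")[[1]]
  n <- length(ch)
  if (n <= 2L) return(paste(ch, collapse = ""))
  for (try in seq_len(maxTries)) {
    edges <- split(seq_len(n - 1L), ch[seq_len(n - 1L)])
    ## per-source randomized order of outgoing edges
    edges <- lapply(edges, function(ix) sample(ix))
    ptr <- lapply(edges, function(ix) 1L)
    cur <- ch[1]
    walk <- character(n)
    walk[1] <- cur
    okWalk <- TRUE
    for (k in 2:n) {
      ix <- edges[[cur]]
      p <- ptr[[cur]]
      if (is.null(ix) || p > length(ix)) { okWalk <- FALSE; break }
      ptr[[cur]] <- p + 1L
      nxt <- ch[ix[p] + 1L]
      walk[k] <- nxt
      cur <- nxt
    }
    if (okWalk) return(paste(walk, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian walk")
}
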