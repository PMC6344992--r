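#' Normalize a gene symbol
#'
#' Trims whitespace and applies the mouse title-case convention (first
#' letter upper, rest lower), so list entries like "RPS29" and "rps29"
#' collapse to "Rps29" before cross-study counting.
#'
#' @param s character vector of symbols.
#' @return normalized symbols.
#' @export
normalizeSymbol <- function(s) {
  s <- trimws(s)
  paste0(toupper(substring(s, 1, 1)), tolower(substring(s, 2)))
}

#' A study's dendritic gene list
#'
#' @param studyId study label.
#' @param genes character vector of gene symbols (normalized and
#'   deduplicated on construction).
#' @return list with \code{study_id} and \code{genes}.
#' @export
studyGeneList <- function(studyId, genes) {
  genes <- unique(normalizeSymbol(genes))
  genes <- genes[nzchar(genes)]
  list(study_id = studyId, genes = genes)
}

#' Read per-study gene lists from TSV files
#'
#' Each file must have a \code{gene} column; the study id defaults to the
#' file base name.
#'
#' @param paths character vector of TSV paths.
#' @param studyIds optional study labels (default: base names).
#' @return list of \code{\link{studyGeneList}} objects.
#' @export
readStudyGeneLists <- function(paths, studyIds = NULL) {
  if (is.null(studyIds))
    studyIds <- tools::file_path_sans_ext(basename(paths))
  mapply(function(p, id) {
    tab <- utils::read.delim(p)
    stopifnot("gene" %in% colnames(tab))
    studyGeneList(id, tab$gene)
  }, paths, studyIds, SIMPLIFY = FALSE)
}

#' Integrate dendritic gene lists across studies
#'
#' Unions the per-study gene sets into an observation table counting, for
#' every gene, the number of studies reporting it. Empty lists are dropped
#' with a warning. Ordering is deterministic: observation count descending,
#' then symbol; permuting the input order cannot change the result.
#'
#' @param lists list of \code{\link{studyGeneList}} objects (at least 2
#'   non-empty).
#' @return data.frame: symbol, n_obs, study_ids (comma-joined sorted
#'   labels).
#' @export
integrateStudies <- function(lists) {
  empty <- vapply(lists, function(l) length(l$genes) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " empty study list(s) excluded")
    lists <- lists[!empty]
  }
  if (length(lists) < 2L) stop("at least two non-empty study lists required")
  long <- do.call(rbind, lapply(lists, function(l) {
    data.frame(symbol = l$genes, study = l$study_id)
  }))
  byGene <- split(long$study, long$symbol)
  tab <- data.frame(
    symbol = names(byGene),
    n_obs = vapply(byGene, function(s) length(unique(s)), integer(1)),
    study_ids = vapply(byGene, function(s) {
      paste(sort(unique(s)), collapse = ",")
    }, character(1)),
    row.names = NULL)
  tab[order(-tab$n_obs, tab$symbol), , drop = FALSE]
}
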