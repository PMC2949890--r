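# GMT (gene-matrix-transposed) export of annotation gene sets.

#' Write gene sets in GMT format
#'
#' One tab-delimited row per retained term that annotates at least one
#' gene: term id, description (the term name when an ontology is supplied,
#' otherwise `NA`), then the member genes. The gene-to-term mapping is
#' taken verbatim from the annotation set — clipping a subset never alters
#' which genes a surviving term carries.
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @param retained Character vector of term ids to export, or `NULL` for
#'   every annotated term.
#' @param dag Optional [ontology_dag()] used to fill the description
#'   column with term names.
#' @return `path`, invisibly. Terms with zero associated genes produce no
#'   row.
#' @export
write_gmt <- function(annotations, path, retained = NULL, dag = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  g2t <- genes_per_term(annotations)
  terms <- names(g2t)
  if (!is.null(retained)) terms <- intersect(terms, as.character(retained))
  terms <- sort(terms)
  rows <- character(0)
  for (t in terms) {
    genes <- g2t[[t]]
    if (length(genes) == 0L) next
    desc <- "NA"
    if (!is.null(dag)) {
      nm <- dag$terms$name[match(t, dag$terms$id)]
      if (!is.na(nm)) desc <- nm
    }
    rows <- c(rows, paste(c(t, desc, genes), collapse = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to the tab-delimited GMT file.
#' @return Named list mapping set id to a character vector of member
#'   genes; set descriptions are attached as attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 columns", i))
    }
    out[[parts[1]]] <- parts[-(1:2)]
    desc[parts[1]] <- parts[2]
  }
  attr(out, "descriptions") <- desc
  out
}
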