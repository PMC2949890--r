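# Gene-annotation handling: GAF 2.x reading/writing and derived views.

#' Construct an annotation set
#'
#' Holds gene-to-term association records together with the filtering
#' options used when deriving the gene/term views. Records whose qualifier
#' contains `NOT` are kept in the record table but excluded from the
#' derived views by default, as are records with an excluded evidence code.
#'
#' @param records Data frame with columns `gene` (symbol), `object_id`,
#'   `term`, `evidence`, `qualifier`, `taxon`. Missing optional columns are
#'   filled with `""`.
#' @param exclude_not Exclude `NOT`-qualified records from derived views?
#'   Default `TRUE`.
#' @param evidence_exclude Character vector of evidence codes to exclude
#'   from derived views (e.g. `"IEA"`), or `NULL`.
#' @return An object of class `annotation_set`.
#' @examples
#' anns <- annotation_set(data.frame(
#'   gene = c("g1", "g2"), term = c("T:1", "T:1"),
#'   evidence = "IDA"))
#' genes_per_term(anns)
#' @export
annotation_set <- function(records, exclude_not = TRUE,
                           evidence_exclude = NULL) {
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  need <- c("gene", "term")
  if (!all(need %in% names(records))) {
    stop("'records' must have at least columns gene and term")
  }
  fill <- function(col, default = "") {
    if (col %in% names(records)) as.character(records[[col]])
    else rep(default, nrow(records))
  }
  rec <- data.frame(
    gene = as.character(records$gene),
    object_id = fill("object_id"),
    term = as.character(records$term),
    evidence = fill("evidence"),
    qualifier = fill("qualifier"),
    taxon = fill("taxon"),
    stringsAsFactors = FALSE
  )
  structure(list(records = rec,
                 exclude_not = isTRUE(exclude_not),
                 evidence_exclude = as.character(evidence_exclude %||%
                                                   character())),
            class = "annotation_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation_set <- function(x, ...) {
  act <- active_records(x)
  cat(sprintf(
    "Annotation set: %d records (%d active), %d genes, %d terms\n",
    nrow(x$records), nrow(act), length(unique(act$gene)),
    length(unique(act$term))))
  if (length(x$evidence_exclude)) {
    cat("  evidence excluded:", paste(x$evidence_exclude, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Records that survive the NOT-qualifier and evidence-code filters.
active_records <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  rec <- x$records
  keep <- rep(TRUE, nrow(rec))
  if (x$exclude_not) {
    keep <- keep & !grepl("\\bNOT\\b", rec$qualifier)
  }
  if (length(x$evidence_exclude)) {
    keep <- keep & !(rec$evidence %in% x$evidence_exclude)
  }
  rec[keep, , drop = FALSE]
}

#' Genes annotated to each term
#'
#' @param x An [annotation_set()].
#' @param key Key genes by `"gene"` symbol (default) or `"object_id"`.
#' @return Named list mapping term id to a sorted vector of unique gene
#'   keys; derived after the NOT/evidence filters.
#' @export
genes_per_term <- function(x, key = c("gene", "object_id")) {
  key <- match.arg(key)
  rec <- active_records(x)
  sp <- split(rec[[key]], rec$term)
  out <- lapply(sp, function(v) sort(unique(v)))
  out[order(names(out))]
}

#' Terms annotating each gene
#'
#' @inheritParams genes_per_term
#' @return Named list mapping gene key to a sorted vector of unique term
#'   ids; derived after the NOT/evidence filters.
#' @export
terms_per_gene <- function(x, key = c("gene", "object_id")) {
  key <- match.arg(key)
  rec <- active_records(x)
  sp <- split(rec$term, rec[[key]])
  out <- lapply(sp, function(v) sort(unique(v)))
  out[order(names(out))]
}

#' Term ids used by an annotation set
#'
#' @param x An [annotation_set()].
#' @return Sorted unique term ids among the active (filtered) records.
#' @export
annotated_terms <- function(x) {
  sort(unique(active_records(x)$term))
}

#' Read a GAF 2.x gene association file
#'
#' Captures the object id, symbol, qualifier, GO id, evidence code and
#' taxon columns of the tab-delimited Gene Association File format.
#' Comment lines start with `!`. Rows must have 15 to 17 columns (GAF 2.0
#' through 2.2); anything else is an error naming the line.
#'
#' @param path Path to the GAF file.
#' @param exclude_not,evidence_exclude Passed to [annotation_set()].
#' @return An [annotation_set()].
#' @export
read_gaf <- function(path, exclude_not = TRUE, evidence_exclude = NULL) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- read_text_lines(path)
  keep <- !grepl("^!", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(annotation_set(data.frame(gene = character(),
                                     term = character()),
                          exclude_not, evidence_exclude))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 15L | nf > 17L)
  if (length(bad)) {
    stop(sprintf("GAF line %d has %d columns (expected 15-17)",
                 lineno[bad[1]], nf[bad[1]]))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  rec <- data.frame(
    gene = col(3), object_id = col(2), term = col(5),
    evidence = col(7), qualifier = col(4), taxon = col(13),
    stringsAsFactors = FALSE
  )
  annotation_set(rec, exclude_not, evidence_exclude)
}

#' Write an annotation set as GAF 2.2
#'
#' @param x An [annotation_set()]. All records are written, including
#'   `NOT`-qualified ones.
#' @param path Output path.
#' @param db Value for the database column (column 1).
#' @return `path`, invisibly.
#' @export
write_gaf <- function(x, path, db = "ontoclip") {
  stopifnot(inherits(x, "annotation_set"))
  rec <- x$records
  today <- format(Sys.Date(), "%Y%m%d")
  rows <- vapply(seq_len(nrow(rec)), function(i) {
    paste(c(db, rec$object_id[i], rec$gene[i], rec$qualifier[i],
            rec$term[i], "REF:0000000", rec$evidence[i], "", "P",
            "", "", "protein", rec$taxon[i], today, db, "", ""),
          collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Read a flat term-id list
#'
#' One id per line; `#` starts a comment; blank lines and duplicates are
#' dropped. Used for expert decision lists and subset term inventories. An
#' empty file yields an empty set.
#'
#' @param path Path to the list file.
#' @return Sorted character vector of unique ids.
#' @export
read_term_list <- function(path) {
  if (!file.exists(path)) stop("term list not found: ", path)
  lines <- read_text_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  sort(unique(lines[nzchar(lines)]))
}

#' Read a flat gene list
#'
#' Same format as [read_term_list()]: one symbol per line, `#` comments.
#'
#' @param path Path to the list file.
#' @return Sorted character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  read_term_list(path)
}

#' Write a flat term or gene list
#'
#' @param ids Character vector to write, one per line (sorted, unique).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_list <- function(ids, path) {
  writeLines(sort(unique(as.character(ids))), path)
  invisible(path)
}

# readLines with CRLF normalisation and UTF-8.
read_text_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sub("\r$", "", lines)
}
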