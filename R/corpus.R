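#' classfx: drug-class adverse event signals from literature co-mentions
#'
#' Extracts drug and adverse-event (ADE) mentions from MeSH-style indexed
#' citation records, aggregates drugs into ATC-style classes and ADE terms
#' into second-level hierarchy classes, computes proportional reporting
#' ratios (PRR) over article-level 2x2 tables at drug and class resolution,
#' and classifies each (drug class, ADE) pair as a class effect or not by
#' optimal 1-D two-cluster partitioning of member log-PRRs plus Welch's
#' t-test. A seeded synthetic-corpus generator with planted effects supports
#' end-to-end validation without any external data.
#'
#' @importFrom stats setNames runif var
#' @importFrom utils read.delim write.table
#' @importFrom tools md5sum
#' @keywords internal
"_PACKAGE"

# Qualifier sets are stored as a canonical sorted comma-joined key so that
# annotation identity and duplicate collapsing are cheap string operations.
quals_key <- function(q) {
  q <- unique(as.character(q))
  q <- q[nzchar(q)]
  paste(sort(q), collapse = ",")
}

# vectorized "does this qualifier key contain any of `set`" test
key_has_any <- function(keys, set) {
  if (length(set) == 0L) return(rep(FALSE, length(keys)))
  wrapped <- paste0(",", keys, ",")
  out <- rep(FALSE, length(keys))
  for (q in set) out <- out | grepl(paste0(",", q, ","), wrapped, fixed = TRUE)
  out
}

new_corpus <- function(article_ids, annotations) {
  stopifnot(is.character(article_ids),
            is.data.frame(annotations),
            all(c("article_id", "descriptor_id", "qualifiers") %in%
                  names(annotations)))
  structure(list(article_ids = article_ids,
                 annotations = annotations[, c("article_id", "descriptor_id",
                                               "qualifiers")]),
            class = "classfx_corpus")
}

#' Build a citation corpus in memory
#'
#' A corpus is an ordered collection of citation records. Each record has an
#' opaque article identifier and a set of annotations; each annotation is a
#' descriptor (a controlled-vocabulary heading such as a MeSH descriptor or
#' supplementary concept) plus a possibly empty set of qualifiers (such as
#' \code{"AE"} for \emph{adverse effects} or \code{"CI"} for
#' \emph{chemically induced}).
#'
#' @param records named list: names are article identifiers, each element a
#'   list of annotations. An annotation is either a character vector whose
#'   first element is the descriptor id and remaining elements are qualifier
#'   ids, or a list with elements \code{descriptor} and \code{qualifiers}.
#' @return an object of class \code{classfx_corpus}
#' @examples
#' corpus(list(A1 = list(c("D_oflox", "AE"), c("D_tendinopathy", "CI"))))
#' @export
corpus <- function(records) {
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every record needs a non-empty article id (list names)")
  if (anyDuplicated(ids))
    stop("duplicate article_id: ", ids[duplicated(ids)][1L])
  rows <- lapply(seq_along(records), function(i) {
    anns <- records[[i]]
    if (length(anns) == 0L)
      return(NULL)
    desc <- character(length(anns))
    keys <- character(length(anns))
    for (j in seq_along(anns)) {
      a <- anns[[j]]
      if (is.list(a)) {
        desc[j] <- as.character(a$descriptor)
        keys[j] <- quals_key(a$qualifiers)
      } else {
        desc[j] <- as.character(a[[1L]])
        keys[j] <- quals_key(a[-1L])
      }
    }
    if (any(!nzchar(desc)))
      stop("empty descriptor_id in record ", ids[i])
    data.frame(article_id = ids[i], descriptor_id = desc, qualifiers = keys,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  if (is.null(ann))
    ann <- data.frame(article_id = character(), descriptor_id = character(),
                      qualifiers = character(), stringsAsFactors = FALSE)
  ann <- unique(ann)
  rownames(ann) <- NULL
  new_corpus(ids, ann)
}

#' @export
print.classfx_corpus <- function(x, ...) {
  cat("<classfx_corpus> ", length(x$article_ids), " articles, ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

#' Number of articles in a corpus
#' @param x a \code{classfx_corpus}
#' @export
n_articles <- function(x) length(x$article_ids)

#' Read a citation corpus from a JSON-lines file
#'
#' One article per line:
#' \code{\{"id": "A1", "anns": [["D_oflox", ["AE"]], ...]\}}.
#' Exact duplicate (descriptor, qualifier-set) annotations within a record
#' are collapsed; record order is preserved.
#'
#' @param path path to a JSON-lines citation file
#' @return a \code{classfx_corpus}
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(new_corpus(character(),
                      data.frame(article_id = character(),
                                 descriptor_id = character(),
                                 qualifiers = character(),
                                 stringsAsFactors = FALSE)))
  recs <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$id) || !nzchar(as.character(rec$id)))
      stop("malformed citation record at line ", lineno[i])
    ids[i] <- as.character(rec$id)
    anns <- rec$anns
    if (is.null(anns)) anns <- list()
    recs[[i]] <- lapply(anns, function(a) {
      if (length(a) < 1L || !nzchar(as.character(a[[1L]])))
        stop("malformed annotation at line ", lineno[i])
      q <- if (length(a) >= 2L) unlist(a[[2L]], use.names = FALSE) else character()
      list(descriptor = as.character(a[[1L]]), qualifiers = as.character(q))
    })
  }
  if (anyDuplicated(ids))
    stop("duplicate article_id: ", ids[duplicated(ids)][1L])
  names(recs) <- ids
  corpus(recs)
}

#' Write a corpus to a JSON-lines file
#'
#' Inverse of \code{\link{read_corpus}}: reading the written file yields a
#' corpus identical to the input (annotations in canonical sorted-qualifier
#' form).
#'
#' @param x a \code{classfx_corpus}
#' @param path output path
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "classfx_corpus"))
  ann <- x$annotations
  by_article <- split(seq_len(nrow(ann)), factor(ann$article_id,
                                                 levels = x$article_ids))
  esc <- function(s) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s))
  lines <- vapply(x$article_ids, function(id) {
    idx <- by_article[[id]]
    anns <- if (length(idx) == 0L) "" else paste(vapply(idx, function(i) {
      quals <- strsplit(ann$qualifiers[i], ",", fixed = TRUE)[[1L]]
      qjson <- if (length(quals) == 0L) "[]" else
        paste0("[", paste0('"', esc(quals), '"', collapse = ","), "]")
      paste0('["', esc(ann$descriptor_id[i]), '",', qjson, "]")
    }, character(1)), collapse = ",")
    paste0('{"id":"', esc(id), '","anns":[', anns, "]}")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Plain tab-separated output with a header row. Numeric columns keep full
#' precision (15 significant digits) so that reading the file back
#' reproduces the values.
#'
#' @param rows a data.frame of uniform records
#' @param path output path
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format(out[[j]], digits = 15,
                                                trim = TRUE, scientific = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV table written by \code{write_table}
#' @param path path to a TSV file with a header row
#' @return a data.frame
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = NA)
}
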