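#' Build the analysis universe
#'
#' The denominator population for all contingency tables: articles with at
#' least one drug mention and at least one ADE mention. Incidence of
#' ingredients and ADE terms over these articles is held as sparse
#' article-by-entity matrices so tables at every resolution reduce to
#' column sums and cross products.
#'
#' @param mentions a \code{classfx_mentions}
#' @return an object of class \code{classfx_universe}
#' @export
build_universe <- function(mentions) {
  stopifnot(inherits(mentions, "classfx_mentions"))
  ids <- setdiff(mentions$article_ids, mentions$incomplete)
  if (length(ids) == 0L)
    stop("empty universe: no article has both a drug and an ADE mention")
  drugs <- mentions$drugs[mentions$drugs$article_id %in% ids, ]
  ades <- mentions$ades[mentions$ades$article_id %in% ids, ]
  ingredients <- sort(unique(drugs$ingredient_id))
  terms <- sort(unique(ades$term_id))
  dpairs <- unique(data.frame(i = match(drugs$article_id, ids),
                              j = match(drugs$ingredient_id, ingredients)))
  apairs <- unique(data.frame(i = match(ades$article_id, ids),
                              j = match(ades$term_id, terms)))
  drug_mat <- Matrix::sparseMatrix(i = dpairs$i, j = dpairs$j, x = 1,
                                   dims = c(length(ids), length(ingredients)),
                                   dimnames = list(ids, ingredients))
  ade_mat <- Matrix::sparseMatrix(i = apairs$i, j = apairs$j, x = 1,
                                  dims = c(length(ids), length(terms)),
                                  dimnames = list(ids, terms))
  structure(list(article_ids = ids, drug_mat = drug_mat, ade_mat = ade_mat,
                 ingredients = ingredients, ade_terms = terms),
            class = "classfx_universe")
}

#' @export
print.classfx_universe <- function(x, ...) {
  cat("<classfx_universe> ", length(x$article_ids), " articles, ",
      length(x$ingredients), " ingredients, ", length(x$ade_terms),
      " ADE terms\n", sep = "")
  invisible(x)
}

#' Article-level predicates over a universe
#'
#' \code{has_drug} is TRUE for articles mentioning any of the given
#' ingredients (after normalization); \code{has_ade} for articles
#' mentioning any of the given ADE terms. These are the row/column
#' predicates of the 2x2 tables at both drug and class resolution.
#'
#' @param universe a \code{classfx_universe}
#' @param ingredients,terms entity ids defining the predicate
#' @return logical vector aligned with \code{universe$article_ids}
#' @export
has_drug <- function(universe, ingredients) {
  stopifnot(inherits(universe, "classfx_universe"))
  cols <- intersect(as.character(ingredients), universe$ingredients)
  if (length(cols) == 0L) return(rep(FALSE, length(universe$article_ids)))
  Matrix::rowSums(universe$drug_mat[, cols, drop = FALSE]) > 0
}

#' @rdname has_drug
#' @export
has_ade <- function(universe, terms) {
  stopifnot(inherits(universe, "classfx_universe"))
  cols <- intersect(as.character(terms), universe$ade_terms)
  if (length(cols) == 0L) return(rep(FALSE, length(universe$article_ids)))
  Matrix::rowSums(universe$ade_mat[, cols, drop = FALSE]) > 0
}

#' Build a 2x2 contingency table over the universe
#'
#' Counts articles by row predicate (mentioning the drug or any member of
#' the drug class) against column predicate (mentioning the ADE or any
#' term of the ADE class): \code{a} = both, \code{b} = row only, \code{c} =
#' column only, \code{d} = neither. The four cells always partition the
#' universe.
#'
#' @param universe a \code{classfx_universe}
#' @param row_predicate,col_predicate logical vectors aligned with the
#'   universe's articles, or functions mapping an article id to a logical
#' @return an object of class \code{classfx_table} with fields a, b, c, d
#' @export
contingency <- function(universe, row_predicate, col_predicate) {
  stopifnot(inherits(universe, "classfx_universe"))
  as_vec <- function(p) {
    if (is.function(p))
      p <- vapply(universe$article_ids, p, logical(1), USE.NAMES = FALSE)
    stopifnot(is.logical(p), length(p) == length(universe$article_ids),
              !anyNA(p))
    p
  }
  r <- as_vec(row_predicate)
  k <- as_vec(col_predicate)
  structure(list(a = sum(r & k), b = sum(r & !k), c = sum(!r & k),
                 d = sum(!r & !k), corrected = FALSE),
            class = "classfx_table")
}

#' @export
print.classfx_table <- function(x, ...) {
  cat("<classfx_table> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      if (x$corrected) " (0.5-corrected)" else "", "\n", sep = "")
  invisible(x)
}

#' Proportional reporting ratio of a 2x2 table
#'
#' \code{PRR = (a/(a+b)) / (c/(c+d))}: the rate of the event among articles
#' mentioning the drug (class) relative to its rate among the remaining
#' articles. When \code{b} or \code{c} is zero the usual zero-cell
#' correction adds 0.5 to all four cells first, keeping the ratio finite.
#'
#' @param table a \code{classfx_table}, or a numeric vector/list with
#'   elements a, b, c, d
#' @return list with elements \code{prr}, \code{corrected} (logical) and
#'   \code{table} (the possibly corrected cells)
#' @export
prr <- function(table) {
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (any(is.na(c(a, b, cc, d)))) stop("incomplete contingency table")
  if (a + b < 1 || cc + d < 1)
    stop("undefined proportion: a+b and c+d must both be >= 1")
  corrected <- (b == 0 || cc == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  value <- (a / (a + b)) / (cc / (cc + d))
  list(prr = value, corrected = corrected,
       table = structure(list(a = a, b = b, c = cc, d = d,
                              corrected = corrected),
                         class = "classfx_table"))
}

signal_levels <- c("drug_x_ade", "drug_x_ade_class", "class_x_ade",
                   "class_x_ade_class")

# article-by-entity incidence at the requested resolution
row_incidence <- function(universe, level_rows, class_members) {
  if (level_rows == "drug") return(universe$drug_mat)
  if (is.null(class_members) || length(class_members) == 0L)
    stop("class-level rows need non-empty class_members")
  classes <- names(class_members)
  long <- data.frame(
    ingredient_id = unlist(class_members, use.names = FALSE),
    class_id = rep(classes, lengths(class_members)),
    stringsAsFactors = FALSE)
  long <- long[long$ingredient_id %in% universe$ingredients, ]
  memb <- Matrix::sparseMatrix(
    i = match(long$ingredient_id, universe$ingredients),
    j = match(long$class_id, classes), x = 1,
    dims = c(length(universe$ingredients), length(classes)),
    dimnames = list(universe$ingredients, classes))
  inc <- universe$drug_mat %*% memb
  inc@x <- rep(1, length(inc@x))
  inc
}

col_incidence <- function(universe, level_cols, ade_vocab) {
  if (level_cols == "ade") return(universe$ade_mat)
  if (is.null(ade_vocab)) stop("ADE-class columns need the ADE vocabulary")
  map <- ade_class_map(ade_vocab)
  map <- map[map$term_id %in% universe$ade_terms, ]
  classes <- sort(unique(map$class_id))
  t2c <- Matrix::sparseMatrix(
    i = match(map$term_id, universe$ade_terms),
    j = match(map$class_id, classes), x = 1,
    dims = c(length(universe$ade_terms), length(classes)),
    dimnames = list(universe$ade_terms, classes))
  inc <- universe$ade_mat %*% t2c
  inc@x <- rep(1, length(inc@x))
  inc
}

#' Scan all co-occurring pairs for disproportionality signals
#'
#' Builds the 2x2 table for every (row entity, column event) pair that
#' co-occurs in at least one article (\code{a >= 1}) at the requested
#' resolution and computes its PRR and natural-log PRR. Pairs that never
#' co-occur get no record (their PRR is the neutral value 1 and appears as
#' \code{ln 1 = 0} only when a dense matrix is materialized). The reported
#' a, b, c, d are the uncorrected article counts; \code{prr} reflects the
#' 0.5 correction when \code{corrected} is TRUE.
#'
#' @param universe a \code{classfx_universe}
#' @param level one of \code{"drug_x_ade"}, \code{"drug_x_ade_class"},
#'   \code{"class_x_ade"}, \code{"class_x_ade_class"}
#' @param ade_vocab a \code{classfx_ade_vocab}; required for
#'   \code{*_ade_class} levels
#' @param class_members named list (class id -> member ingredient ids) as
#'   returned by \code{\link{eligible_classes}}; required for
#'   \code{class_*} levels
#' @return data.frame of signal records: level, row_id, col_id, a, b, c, d,
#'   corrected, prr, log_prr
#' @export
signal_scan <- function(universe, level = "drug_x_ade", ade_vocab = NULL,
                        class_members = NULL) {
  stopifnot(inherits(universe, "classfx_universe"))
  level <- match.arg(level, signal_levels)
  parts <- strsplit(level, "_x_", fixed = TRUE)[[1L]]
  R <- row_incidence(universe, parts[1L], class_members)
  C <- col_incidence(universe, parts[2L], ade_vocab)
  n <- length(universe$article_ids)
  A <- as(Matrix::crossprod(R, C), "TsparseMatrix")
  if (length(A@x) == 0L)
    return(data.frame(level = character(), row_id = character(),
                      col_id = character(), a = numeric(), b = numeric(),
                      c = numeric(), d = numeric(), corrected = logical(),
                      prr = numeric(), log_prr = numeric(),
                      stringsAsFactors = FALSE))
  row_tot <- Matrix::colSums(R)
  col_tot <- Matrix::colSums(C)
  keep <- A@x > 0            # drop any explicit structural zeros
  ri <- A@i[keep] + 1L
  ci <- A@j[keep] + 1L
  a <- A@x[keep]
  b <- row_tot[ri] - a
  cc <- col_tot[ci] - a
  d <- n - a - b - cc
  corrected <- (b == 0) | (cc == 0)
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- cc + 0.5 * corrected; d2 <- d + 0.5 * corrected
  prr_v <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  out <- data.frame(level = level, row_id = rownames(A)[ri],
                    col_id = colnames(A)[ci], a = a, b = unname(b),
                    c = unname(cc), d = unname(d), corrected = corrected,
                    prr = unname(prr_v), log_prr = unname(log(prr_v)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$row_id, out$col_id), ]
  rownames(out) <- NULL
  out
}

#' Dense log-PRR matrix from signal records
#'
#' Cells without a record hold \code{ln 1 = 0}, the neutral PRR of pairs
#' that never co-occur.
#'
#' @param records data.frame of signal records from \code{\link{signal_scan}}
#' @param row_ids,col_ids axis identities; default all ids present in
#'   \code{records}
#' @return numeric matrix of log-PRR values with dimnames
#' @export
to_matrix <- function(records, row_ids = NULL, col_ids = NULL) {
  if (length(unique(records$level)) > 1L)
    stop("records mix resolutions: ",
         paste(unique(records$level), collapse = ", "))
  if (is.null(row_ids)) row_ids <- sort(unique(records$row_id))
  if (is.null(col_ids)) col_ids <- sort(unique(records$col_id))
  keep <- records$row_id %in% row_ids & records$col_id %in% col_ids
  records <- records[keep, ]
  if (anyDuplicated(paste(records$row_id, records$col_id, sep = "\r")))
    stop("duplicate (row, col) signal records")
  m <- matrix(0, nrow = length(row_ids), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(records) > 0L)
    m[cbind(match(records$row_id, row_ids),
            match(records$col_id, col_ids))] <- records$log_prr
  m
}
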