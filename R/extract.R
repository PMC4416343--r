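#' Extraction rules for drug and ADE mentions
#'
#' A descriptor counts as a drug mention when it maps to an ingredient and
#' carries at least one qualifier in \code{drug_qualifiers} (default
#' \code{"AE"}, \emph{adverse effects}). A descriptor counts as an ADE
#' mention when it is in the ADE vocabulary and either carries a qualifier
#' in \code{ade_qualifiers} (default \code{"CI"}, \emph{chemically induced})
#' or is itself inherently indicative of an adverse event (e.g. a
#' drug-induced liver injury heading), regardless of qualifiers.
#'
#' @param drug_qualifiers qualifier ids marking the drug role
#' @param ade_qualifiers qualifier ids marking the manifestation role
#' @param inherent_ade_descriptors descriptor ids that denote an ADE by
#'   themselves
#' @return an object of class \code{classfx_rules}
#' @export
extraction_rules <- function(drug_qualifiers = "AE", ade_qualifiers = "CI",
                             inherent_ade_descriptors = character()) {
  if (length(drug_qualifiers) == 0L || length(ade_qualifiers) == 0L)
    stop("drug_qualifiers and ade_qualifiers must be non-empty")
  structure(list(drug_qualifiers = as.character(drug_qualifiers),
                 ade_qualifiers = as.character(ade_qualifiers),
                 inherent_ade_descriptors = as.character(inherent_ade_descriptors)),
            class = "classfx_rules")
}

#' Extract per-article drug and ADE mentions
#'
#' Applies the extraction rules to every record: drug mentions are
#' vocabulary-mapped descriptors carrying a drug-role qualifier; ADE
#' mentions are ADE-vocabulary descriptors carrying a manifestation-role
#' qualifier or listed as inherently indicative. Descriptors unknown to
#' both vocabularies are ignored (real indexing carries many irrelevant
#' headings). Articles lacking one side are retained — they still belong to
#' denominator counts — and are listed in the \code{incomplete} field.
#'
#' @param corpus a \code{classfx_corpus}
#' @param rules a \code{classfx_rules}
#' @param drug_vocab a \code{classfx_drug_vocab}
#' @param ade_vocab a \code{classfx_ade_vocab}
#' @param verbose if TRUE, report the number of ignored descriptors
#' @return an object of class \code{classfx_mentions} with per-article drug
#'   mention and ADE mention tables
#' @export
extract_mentions <- function(corpus, rules, drug_vocab, ade_vocab,
                             verbose = FALSE) {
  stopifnot(inherits(corpus, "classfx_corpus"),
            inherits(rules, "classfx_rules"),
            inherits(drug_vocab, "classfx_drug_vocab"),
            inherits(ade_vocab, "classfx_ade_vocab"))
  ann <- corpus$annotations
  ing <- normalize_drug(drug_vocab, ann$descriptor_id)
  is_drug <- !is.na(ing) & key_has_any(ann$qualifiers, rules$drug_qualifiers)
  in_ade_vocab <- ann$descriptor_id %in% ade_terms(ade_vocab)
  is_ade <- in_ade_vocab &
    (key_has_any(ann$qualifiers, rules$ade_qualifiers) |
       ann$descriptor_id %in% rules$inherent_ade_descriptors)
  if (verbose) {
    ignored <- sum(is.na(ing) & !in_ade_vocab)
    message("extract_mentions: ", ignored,
            " annotations ignored (descriptor in neither vocabulary)")
  }
  drugs <- unique(data.frame(article_id = ann$article_id[is_drug],
                             term_id = ann$descriptor_id[is_drug],
                             ingredient_id = ing[is_drug],
                             stringsAsFactors = FALSE))
  ades <- unique(data.frame(article_id = ann$article_id[is_ade],
                            term_id = ann$descriptor_id[is_ade],
                            stringsAsFactors = FALSE))
  rownames(drugs) <- rownames(ades) <- NULL
  incomplete <- setdiff(corpus$article_ids,
                        intersect(drugs$article_id, ades$article_id))
  structure(list(article_ids = corpus$article_ids, drugs = drugs,
                 ades = ades, incomplete = incomplete),
            class = "classfx_mentions")
}

#' @export
print.classfx_mentions <- function(x, ...) {
  cat("<classfx_mentions> ", length(x$article_ids), " articles; ",
      nrow(x$drugs), " drug mentions; ", nrow(x$ades), " ADE mentions; ",
      length(x$incomplete), " articles lack one side\n", sep = "")
  invisible(x)
}

#' Enumerate within-article drug-ADE pairs
#'
#' The per-article cross product of drug mentions and ADE mentions, the
#' standard co-mention convention: an article indexed with two drugs and
#' three ADE manifestations contributes six pairs. Pairs are deduplicated
#' within an article; the same pair in two articles yields two rows.
#'
#' @param mentions a \code{classfx_mentions}
#' @return data.frame with columns \code{article_id}, \code{drug_term},
#'   \code{ade_term}, \code{ingredient_id}
#' @export
extract_pairs <- function(mentions) {
  stopifnot(inherits(mentions, "classfx_mentions"))
  m <- merge(mentions$drugs, mentions$ades, by = "article_id",
             suffixes = c("_drug", "_ade"))
  out <- data.frame(article_id = m$article_id,
                    drug_term = m$term_id_drug,
                    ade_term = m$term_id_ade,
                    ingredient_id = m$ingredient_id,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(match(out$article_id, mentions$article_ids),
                   out$drug_term, out$ade_term), ]
  rownames(out) <- NULL
  out
}
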