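#' Build a drug vocabulary
#'
#' Holds the terminology relations used to normalize drug terms found in
#' citation records: term -> ingredient, precise-ingredient (PIN) ->
#' ingredient (IN), ingredient -> drug codes (ATC-style 5th-level codes),
#' and code -> class (4th-level class). The PIN -> IN map is transitively
#' closed at load time so normalization resolves in one lookup; cycles are
#' rejected.
#'
#' @param term_to_ingredient data.frame with columns \code{term_id},
#'   \code{ingredient_id}
#' @param pin_to_in data.frame with columns \code{pin_ingredient_id},
#'   \code{ingredient_id}; may be empty
#' @param ingredient_codes data.frame with columns \code{ingredient_id},
#'   \code{code_id}
#' @param code_classes data.frame with columns \code{code_id},
#'   \code{class_id}, \code{class_name}
#' @return an object of class \code{classfx_drug_vocab}
#' @export
drug_vocabulary <- function(term_to_ingredient, pin_to_in = NULL,
                            ingredient_codes = NULL, code_classes = NULL) {
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (is.null(pin_to_in))
    pin_to_in <- empty(pin_ingredient_id = character(),
                       ingredient_id = character())
  if (is.null(ingredient_codes))
    ingredient_codes <- empty(ingredient_id = character(),
                              code_id = character())
  if (is.null(code_classes))
    code_classes <- empty(code_id = character(), class_id = character(),
                          class_name = character())
  stopifnot(all(c("term_id", "ingredient_id") %in% names(term_to_ingredient)),
            all(c("pin_ingredient_id", "ingredient_id") %in% names(pin_to_in)),
            all(c("ingredient_id", "code_id") %in% names(ingredient_codes)),
            all(c("code_id", "class_id") %in% names(code_classes)))

  # transitive closure of PIN -> IN; bounded iteration detects cycles
  pin <- setNames(as.character(pin_to_in$ingredient_id),
                  as.character(pin_to_in$pin_ingredient_id))
  if (length(pin) > 0L) {
    for (step in seq_len(length(pin) + 1L)) {
      nxt <- pin[pin]
      hop <- !is.na(nxt) & nxt != pin
      if (!any(hop)) break
      if (step > length(pin)) stop("pin_to_in contains a cycle")
      pin[hop] <- nxt[hop]
    }
    if (any(names(pin) == pin)) stop("pin_to_in contains a cycle (self-loop)")
  }

  missing_codes <- setdiff(ingredient_codes$code_id, code_classes$code_id)
  if (length(missing_codes) > 0L)
    stop("codes without a class: ", paste(missing_codes, collapse = ", "))

  term2ing <- setNames(as.character(term_to_ingredient$ingredient_id),
                       as.character(term_to_ingredient$term_id))
  ing2codes <- split(as.character(ingredient_codes$code_id),
                     as.character(ingredient_codes$ingredient_id))
  code2class <- setNames(as.character(code_classes$class_id),
                         as.character(code_classes$code_id))
  class_names <- setNames(as.character(code_classes$class_name),
                          as.character(code_classes$class_id))
  resolve <- function(x) {
    hop <- pin[x]
    ifelse(is.na(hop), x, hop)
  }
  ingredients <- unique(c(resolve(unname(term2ing)), names(ing2codes),
                          unname(pin)))
  structure(list(term2ing = term2ing, pin = pin, ing2codes = ing2codes,
                 code2class = code2class, class_names = class_names,
                 ingredients = ingredients),
            class = "classfx_drug_vocab")
}

#' @export
print.classfx_drug_vocab <- function(x, ...) {
  cat("<classfx_drug_vocab> ", length(x$term2ing), " terms, ",
      length(x$ingredients), " ingredients, ",
      length(unique(x$code2class)), " classes\n", sep = "")
  invisible(x)
}

#' Normalize drug terms to ingredients
#'
#' Maps a descriptor/term id to its base ingredient: first through the
#' term -> ingredient table, then through the closed PIN -> IN map (so a
#' salt or ester resolves to its active moiety, e.g. a valproic-acid term
#' resolves to the valproate ingredient). A known ingredient id normalizes
#' to itself; anything unmapped yields \code{NA}.
#'
#' @param vocab a \code{classfx_drug_vocab}
#' @param term_ids character vector of term or ingredient ids
#' @return character vector of ingredient ids (\code{NA} where unmapped)
#' @export
normalize_drug <- function(vocab, term_ids) {
  stopifnot(inherits(vocab, "classfx_drug_vocab"))
  term_ids <- as.character(term_ids)
  ing <- unname(vocab$term2ing[term_ids])
  # an ingredient (or PIN) id passed directly needs no term lookup
  direct <- is.na(ing) &
    (term_ids %in% vocab$ingredients | term_ids %in% names(vocab$pin))
  ing[direct] <- term_ids[direct]
  hop <- unname(vocab$pin[ing])
  take <- !is.na(hop)
  ing[take] <- hop[take]
  ing
}

#' Drug classes of an ingredient
#'
#' Union of the classes of all the ingredient's codes, deduplicated: the
#' ingredient, not the code, is the unit of class membership, so a drug
#' with systemic and topical codes in two classes is a member of both.
#'
#' @param vocab a \code{classfx_drug_vocab}
#' @param ingredient_id a single ingredient id
#' @return character vector of class ids (empty if unknown)
#' @export
drug_classes <- function(vocab, ingredient_id) {
  stopifnot(inherits(vocab, "classfx_drug_vocab"), length(ingredient_id) == 1L)
  codes <- vocab$ing2codes[[as.character(ingredient_id)]]
  if (is.null(codes)) return(character())
  sort(unique(unname(vocab$code2class[codes])))
}

#' Build an adverse-event vocabulary
#'
#' Maps ADE terms to hierarchy tree numbers (dot-separated, e.g.
#' \code{"C05.651.807"}) and back. Every second-level prefix reachable from
#' the term table must itself be owned by a term (the aggregation target),
#' otherwise construction fails.
#'
#' @param term_trees data.frame with columns \code{term_id},
#'   \code{tree_number}; a term may carry several tree numbers
#' @return an object of class \code{classfx_ade_vocab}
#' @export
ade_vocabulary <- function(term_trees) {
  stopifnot(all(c("term_id", "tree_number") %in% names(term_trees)))
  term_trees$term_id <- as.character(term_trees$term_id)
  term_trees$tree_number <- as.character(term_trees$tree_number)
  term2trees <- split(term_trees$tree_number, term_trees$term_id)
  tree2term <- setNames(term_trees$term_id, term_trees$tree_number)
  prefixes <- unique(tree_prefix2(term_trees$tree_number))
  orphan <- setdiff(prefixes, names(tree2term))
  if (length(orphan) > 0L)
    stop("second-level tree prefixes without an owning term: ",
         paste(orphan, collapse = ", "))
  structure(list(term2trees = term2trees, tree2term = tree2term),
            class = "classfx_ade_vocab")
}

#' @export
print.classfx_ade_vocab <- function(x, ...) {
  cat("<classfx_ade_vocab> ", length(x$term2trees), " terms, ",
      length(x$tree2term), " tree numbers\n", sep = "")
  invisible(x)
}

# first two dot-separated components of a tree number; numbers with fewer
# than two components are their own prefix
tree_prefix2 <- function(tree_numbers) {
  vapply(strsplit(tree_numbers, ".", fixed = TRUE), function(p) {
    paste(p[seq_len(min(2L, length(p)))], collapse = ".")
  }, character(1))
}

#' Terms of the ADE vocabulary
#' @param vocab a \code{classfx_ade_vocab}
#' @return character vector of term ids
#' @export
ade_terms <- function(vocab) names(vocab$term2trees)

#' Aggregate an ADE term to its second-level classes
#'
#' Each of the term's tree numbers is truncated to its first two components
#' and mapped to the term owning that prefix (e.g. terms under
#' \code{C05.651} roll up to the muscular-diseases class owning
#' \code{C05.651}). A term sitting exactly at the second level aggregates
#' to itself; a term with several tree numbers contributes to all its
#' second-level classes.
#'
#' @param vocab a \code{classfx_ade_vocab}
#' @param term_id a single ADE term id
#' @return character vector of owning class term ids (empty if the term is
#'   not in the vocabulary)
#' @export
aggregate_ade <- function(vocab, term_id) {
  stopifnot(inherits(vocab, "classfx_ade_vocab"), length(term_id) == 1L)
  trees <- vocab$term2trees[[as.character(term_id)]]
  if (is.null(trees)) return(character())
  sort(unique(unname(vocab$tree2term[tree_prefix2(trees)])))
}

# long (term_id, class_id) map over the whole ADE vocabulary
ade_class_map <- function(vocab) {
  terms <- names(vocab$term2trees)
  rows <- lapply(terms, function(tm) {
    cls <- aggregate_ade(vocab, tm)
    if (length(cls) == 0L) return(NULL)
    data.frame(term_id = tm, class_id = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), class_id = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Drug classes eligible for class-level analysis
#'
#' Restricts class membership to the ingredients actually observed in the
#' corpus and drops classes with fewer than \code{min_members} observed
#' members; small classes do not support a meaningful within-class
#' comparison. Membership is deduplicated by ingredient even when a drug
#' holds multiple codes within one class.
#'
#' @param observed_ingredients character vector of ingredient ids seen in
#'   the corpus
#' @param vocab a \code{classfx_drug_vocab}
#' @param min_members minimum observed member count (default 4)
#' @return named list: class id -> sorted character vector of member
#'   ingredient ids
#' @export
eligible_classes <- function(observed_ingredients, vocab, min_members = 4L) {
  stopifnot(inherits(vocab, "classfx_drug_vocab"))
  observed <- unique(as.character(observed_ingredients))
  rows <- lapply(observed, function(ing) {
    cls <- drug_classes(vocab, ing)
    if (length(cls) == 0L) return(NULL)
    data.frame(class_id = cls, ingredient_id = ing, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  if (is.null(long)) return(setNames(list(), character()))
  members <- lapply(split(long$ingredient_id, long$class_id),
                    function(m) sort(unique(m)))
  members <- members[vapply(members, length, integer(1)) >= min_members]
  members[order(names(members))]
}

#' Read a drug vocabulary from TSV tables
#'
#' @param drug_terms path to TSV (term_id, ingredient_id)
#' @param pin_to_in path to TSV (pin_ingredient_id, ingredient_id), optional
#' @param ingredient_codes path to TSV (ingredient_id, code_id)
#' @param code_classes path to TSV (code_id, class_id, class_name)
#' @return a \code{classfx_drug_vocab}
#' @export
read_drug_vocabulary <- function(drug_terms, pin_to_in = NULL,
                                 ingredient_codes = NULL, code_classes = NULL) {
  rd <- function(p) if (is.null(p)) NULL else read_table(p)
  drug_vocabulary(read_table(drug_terms), rd(pin_to_in),
                  rd(ingredient_codes), rd(code_classes))
}

#' Read an ADE vocabulary from a TSV table
#' @param ade_trees path to TSV (term_id, tree_number)
#' @return a \code{classfx_ade_vocab}
#' @export
read_ade_vocabulary <- function(ade_trees) {
  ade_vocabulary(read_table(ade_trees))
}
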