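# run code under a temporary RNG state so generation is reproducible and
# leaves the caller's stream untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic citation-corpus generator
#'
#' Describes a corpus of MeSH-style indexed articles with known ground
#' truth. Each article mentions one or two drugs (with the adverse-effects
#' qualifier); every ADE term is then included (with the chemically-induced
#' qualifier) with probability \code{baseline_ade_prob} scaled by the
#' largest relative risk any of the article's drugs carries for that term,
#' capped at 1. Planted effects raise the relative risk of all terms of one
#' ADE class either for every member of a drug class (a class effect) or
#' for a leading fraction of its members (a subset effect). Defaults give a
#' corpus large enough that per-pair co-occurrence counts are in the
#' hundreds, the regime the PRR is meant for.
#'
#' @param n_classes number of drug classes
#' @param members_per_class ingredients generated per class
#' @param n_ade_classes number of second-level ADE classes
#' @param terms_per_ade_class leaf ADE terms under each class
#' @param n_articles corpus size
#' @param baseline_ade_prob per-term mention probability at relative risk 1
#' @param drugs_per_article named numeric vector of probabilities over drug
#'   counts, e.g. \code{c("1" = 0.7, "2" = 0.3)}
#' @param planted_effects data.frame with columns \code{class_id},
#'   \code{ade_class_id}, \code{relative_risk},
#'   \code{affected_member_fraction}, or NULL for a null corpus
#' @param distractor_annotation_rate probability an article carries one
#'   qualifier-less distractor heading outside both vocabularies
#' @param pin_alias_fraction fraction of ingredients given a
#'   precise-ingredient alias (mentions then use the alias half the time,
#'   exercising PIN -> IN normalization end to end)
#' @param seed integer seed; the same configuration always generates the
#'   same vocabularies and corpus
#' @return an object of class \code{classfx_synth_config}
#' @export
synthetic_config <- function(n_classes = 5L, members_per_class = 6L,
                             n_ade_classes = 6L, terms_per_ade_class = 3L,
                             n_articles = 50000L, baseline_ade_prob = 0.05,
                             drugs_per_article = c("1" = 0.7, "2" = 0.3),
                             planted_effects = NULL,
                             distractor_annotation_rate = 0.5,
                             pin_alias_fraction = 0.25, seed = 1L) {
  stopifnot(n_classes >= 1L, members_per_class >= 1L, n_ade_classes >= 1L,
            terms_per_ade_class >= 1L, n_articles >= 1L,
            baseline_ade_prob > 0, baseline_ade_prob <= 1,
            abs(sum(drugs_per_article) - 1) < 1e-8,
            distractor_annotation_rate >= 0, distractor_annotation_rate <= 1,
            pin_alias_fraction >= 0, pin_alias_fraction <= 1)
  if (!is.null(planted_effects)) {
    stopifnot(all(c("class_id", "ade_class_id", "relative_risk",
                    "affected_member_fraction") %in% names(planted_effects)),
              all(planted_effects$relative_risk > 0),
              all(planted_effects$affected_member_fraction > 0),
              all(planted_effects$affected_member_fraction <= 1))
  }
  structure(list(n_classes = as.integer(n_classes),
                 members_per_class = as.integer(members_per_class),
                 n_ade_classes = as.integer(n_ade_classes),
                 terms_per_ade_class = as.integer(terms_per_ade_class),
                 n_articles = as.integer(n_articles),
                 baseline_ade_prob = baseline_ade_prob,
                 drugs_per_article = drugs_per_article,
                 planted_effects = planted_effects,
                 distractor_annotation_rate = distractor_annotation_rate,
                 pin_alias_fraction = pin_alias_fraction,
                 seed = as.integer(seed)),
            class = "classfx_synth_config")
}

synth_ids <- function(config) {
  n_ing <- config$n_classes * config$members_per_class
  list(
    ingredients = sprintf("ING%03d", seq_len(n_ing)),
    classes = sprintf("CLS%02d", seq_len(config$n_classes)),
    ade_classes = sprintf("ADC%02d", seq_len(config$n_ade_classes)),
    ade_terms = as.vector(t(outer(seq_len(config$n_ade_classes),
                                  seq_len(config$terms_per_ade_class),
                                  function(j, k) sprintf("ADE%02d_%02d", j, k)))))
}

#' Generate synthetic drug and ADE vocabularies
#'
#' One ingredient per class member with a drug term mapping to it; a seeded
#' subset of ingredients additionally gets a precise-ingredient alias
#' (term -> PIN ingredient -> base ingredient), and the first ingredient
#' receives a second code in the second class, so one drug is a member of
#' two classes — both standard features of real drug terminologies. ADE
#' terms sit at the third hierarchy level under one second-level parent per
#' ADE class.
#'
#' @param config a \code{classfx_synth_config}
#' @return list with \code{drug_vocab}, \code{ade_vocab}, the raw
#'   \code{tables} (the five TSV-shaped data.frames), and
#'   \code{pin_aliases} (named vector ingredient -> alias term)
#' @export
generate_vocabularies <- function(config) {
  stopifnot(inherits(config, "classfx_synth_config"))
  ids <- synth_ids(config)
  n_ing <- length(ids$ingredients)
  primary_class <- rep(seq_len(config$n_classes),
                       each = config$members_per_class)

  term_to_ingredient <- data.frame(
    term_id = paste0("T_", ids$ingredients),
    ingredient_id = ids$ingredients, stringsAsFactors = FALSE)

  n_pin <- round(config$pin_alias_fraction * n_ing)
  pin_idx <- with_seed(config$seed,
                       if (n_pin > 0) sort(sample.int(n_ing, n_pin)) else integer())
  pin_to_in <- data.frame(pin_ingredient_id = character(),
                          ingredient_id = character(),
                          stringsAsFactors = FALSE)
  if (n_pin > 0) {
    pin_to_in <- data.frame(
      pin_ingredient_id = paste0("PIN_", ids$ingredients[pin_idx]),
      ingredient_id = ids$ingredients[pin_idx], stringsAsFactors = FALSE)
    term_to_ingredient <- rbind(term_to_ingredient, data.frame(
      term_id = paste0("TP_", ids$ingredients[pin_idx]),
      ingredient_id = paste0("PIN_", ids$ingredients[pin_idx]),
      stringsAsFactors = FALSE))
  }

  ingredient_codes <- data.frame(
    ingredient_id = ids$ingredients,
    code_id = sprintf("%sX%03d", ids$classes[primary_class], seq_len(n_ing)),
    stringsAsFactors = FALSE)
  code_classes <- data.frame(
    code_id = ingredient_codes$code_id,
    class_id = ids$classes[primary_class],
    class_name = paste("Class", ids$classes[primary_class]),
    stringsAsFactors = FALSE)
  if (config$n_classes >= 2L) {
    # dual-class drug: first ingredient also coded in the second class
    extra_code <- sprintf("%sX%03dB", ids$classes[2L], 1L)
    ingredient_codes <- rbind(ingredient_codes, data.frame(
      ingredient_id = ids$ingredients[1L], code_id = extra_code,
      stringsAsFactors = FALSE))
    code_classes <- rbind(code_classes, data.frame(
      code_id = extra_code, class_id = ids$classes[2L],
      class_name = paste("Class", ids$classes[2L]), stringsAsFactors = FALSE))
  }

  prefix <- sprintf("C%02d.100", seq_len(config$n_ade_classes))
  ade_trees <- rbind(
    data.frame(term_id = ids$ade_classes, tree_number = prefix,
               stringsAsFactors = FALSE),
    data.frame(
      term_id = ids$ade_terms,
      tree_number = as.vector(t(outer(seq_len(config$n_ade_classes),
                                      seq_len(config$terms_per_ade_class),
                                      function(j, k) sprintf("%s.%03d", prefix[j], k)))),
      stringsAsFactors = FALSE))

  list(drug_vocab = drug_vocabulary(term_to_ingredient, pin_to_in,
                                    ingredient_codes, code_classes),
       ade_vocab = ade_vocabulary(ade_trees),
       tables = list(drug_terms = term_to_ingredient, pin_to_in = pin_to_in,
                     ingredient_codes = ingredient_codes,
                     code_classes = code_classes, ade_trees = ade_trees),
       pin_aliases = if (n_pin > 0)
         setNames(paste0("TP_", ids$ingredients[pin_idx]),
                  ids$ingredients[pin_idx])
       else setNames(character(), character()))
}

# ingredient x ADE-term relative-risk matrix implied by the planted effects
planted_rr_matrix <- function(config) {
  ids <- synth_ids(config)
  R <- matrix(1, nrow = length(ids$ingredients), ncol = length(ids$ade_terms),
              dimnames = list(ids$ingredients, ids$ade_terms))
  pe <- config$planted_effects
  if (is.null(pe)) return(R)
  for (i in seq_len(nrow(pe))) {
    cl <- match(pe$class_id[i], ids$classes)
    ac <- match(pe$ade_class_id[i], ids$ade_classes)
    if (is.na(cl) || is.na(ac))
      stop("planted effect references unknown class or ADE class: ",
           pe$class_id[i], " / ", pe$ade_class_id[i])
    members <- (cl - 1L) * config$members_per_class +
      seq_len(ceiling(pe$affected_member_fraction[i] * config$members_per_class))
    terms <- (ac - 1L) * config$terms_per_ade_class +
      seq_len(config$terms_per_ade_class)
    R[members, terms] <- pe$relative_risk[i]
  }
  R
}

# expected verdict per (realized class membership, ADE class)
synth_pair_truth <- function(config, vocabularies, R) {
  ids <- synth_ids(config)
  members <- eligible_classes(ids$ingredients, vocabularies$drug_vocab,
                              min_members = 1L)
  rows <- list()
  for (cl in names(members)) {
    for (j in seq_len(config$n_ade_classes)) {
      term1 <- (j - 1L) * config$terms_per_ade_class + 1L
      rr <- R[members[[cl]], term1]
      verdict <- if (all(rr == 1)) "null" else
        if (all(rr > 1) && length(unique(rr)) == 1L) "class_effect" else
          "heterogeneous"
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = cl, ade_class_id = ids$ade_classes[j],
        expected_verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic citation corpus with ground truth
#'
#' Samples \code{n_articles} articles under the risk model described in
#' \code{\link{synthetic_config}}. Drug mentions carry the \code{"AE"}
#' qualifier; ADE mentions carry \code{"CI"}; distractor headings carry no
#' qualifier. The same seed always produces a byte-identical corpus.
#'
#' @param config a \code{classfx_synth_config}
#' @param vocabularies output of \code{\link{generate_vocabularies}} for
#'   this config (regenerated when omitted)
#' @return list with \code{corpus} (a \code{classfx_corpus}) and
#'   \code{truth}: the relative-risk matrix \code{rr}, the per-pair
#'   expected verdicts \code{pair_truth}, and the seed
#' @export
generate_corpus <- function(config, vocabularies = NULL) {
  stopifnot(inherits(config, "classfx_synth_config"))
  if (is.null(vocabularies)) vocabularies <- generate_vocabularies(config)
  ids <- synth_ids(config)
  n <- config$n_articles
  n_ing <- length(ids$ingredients)
  n_terms <- length(ids$ade_terms)
  R <- planted_rr_matrix(config)

  dat <- with_seed(config$seed, {
    counts <- sample(as.integer(names(config$drugs_per_article)), n,
                     replace = TRUE, prob = config$drugs_per_article)
    max_drugs <- max(counts)
    drug_idx <- matrix(NA_integer_, nrow = n, ncol = max_drugs)
    drug_idx[, 1L] <- sample.int(n_ing, n, replace = TRUE)
    if (max_drugs >= 2L) {
      for (k in 2:max_drugs) {
        need <- which(counts >= k)
        pick <- sample.int(n_ing, length(need), replace = TRUE)
        # resample collisions with already-chosen drugs of the same article
        repeat {
          clash <- rowSums(drug_idx[need, seq_len(k - 1L), drop = FALSE] ==
                             pick, na.rm = TRUE) > 0
          if (!any(clash)) break
          pick[clash] <- sample.int(n_ing, sum(clash), replace = TRUE)
        }
        drug_idx[need, k] <- pick
      }
    }
    eff <- R[drug_idx[, 1L], , drop = FALSE]
    if (max_drugs >= 2L) {
      for (k in 2:max_drugs) {
        need <- which(!is.na(drug_idx[, k]))
        eff[need, ] <- pmax(eff[need, , drop = FALSE],
                            R[drug_idx[need, k], , drop = FALSE])
      }
    }
    p_mat <- pmin(1, config$baseline_ade_prob * eff)
    hits <- matrix(runif(n * n_terms), nrow = n) < p_mat
    has_dx <- runif(n) < config$distractor_annotation_rate
    dx_term <- sprintf("DX%02d", sample.int(20L, n, replace = TRUE))
    use_alias <- matrix(runif(n * max_drugs) < 0.5, nrow = n)
    list(counts = counts, drug_idx = drug_idx, hits = hits, has_dx = has_dx,
         dx_term = dx_term, use_alias = use_alias)
  })

  article_ids <- sprintf("A%06d", seq_len(n))
  aliases <- vocabularies$pin_aliases
  main_terms <- setNames(paste0("T_", ids$ingredients), ids$ingredients)

  drug_rows <- list()
  for (k in seq_len(ncol(dat$drug_idx))) {
    art <- which(!is.na(dat$drug_idx[, k]))
    if (length(art) == 0L) next
    ing <- ids$ingredients[dat$drug_idx[art, k]]
    term <- unname(main_terms[ing])
    aliased <- ing %in% names(aliases) & dat$use_alias[art, k]
    term[aliased] <- unname(aliases[ing[aliased]])
    drug_rows[[k]] <- data.frame(article_id = article_ids[art],
                                 descriptor_id = term, qualifiers = "AE",
                                 stringsAsFactors = FALSE)
  }
  hit_idx <- which(dat$hits, arr.ind = TRUE)
  ade_rows <- if (nrow(hit_idx) > 0L)
    data.frame(article_id = article_ids[hit_idx[, 1L]],
               descriptor_id = ids$ade_terms[hit_idx[, 2L]],
               qualifiers = "CI", stringsAsFactors = FALSE)
  dx <- which(dat$has_dx)
  dx_rows <- if (length(dx) > 0L)
    data.frame(article_id = article_ids[dx],
               descriptor_id = dat$dx_term[dx], qualifiers = "",
               stringsAsFactors = FALSE)
  ann <- rbind(do.call(rbind, drug_rows), ade_rows, dx_rows)
  ann <- ann[order(match(ann$article_id, article_ids), ann$descriptor_id), ]
  rownames(ann) <- NULL
  corpus <- new_corpus(article_ids, ann)

  truth <- list(rr = R,
                pair_truth = synth_pair_truth(config, vocabularies, R),
                seed = config$seed)
  list(corpus = corpus, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Writes \code{citations.jsonl}, the five terminology TSVs, and
#' \code{truth.tsv} (the expected verdict per class/ADE-class pair) into a
#' directory, ready for \code{\link{run_pipeline}}.
#'
#' @param config a \code{classfx_synth_config}
#' @param dir output directory (created if missing)
#' @return invisibly, a named list of the written paths
#' @export
write_synthetic_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vocabularies <- generate_vocabularies(config)
  gen <- generate_corpus(config, vocabularies)
  paths <- list(
    corpus = file.path(dir, "citations.jsonl"),
    drug_terms = file.path(dir, "drug_terms.tsv"),
    pin_to_in = file.path(dir, "pin_to_in.tsv"),
    ingredient_codes = file.path(dir, "ingredient_codes.tsv"),
    code_classes = file.path(dir, "code_classes.tsv"),
    ade_trees = file.path(dir, "ade_trees.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_corpus(gen$corpus, paths$corpus)
  tb <- vocabularies$tables
  write_table(tb$drug_terms, paths$drug_terms)
  write_table(tb$pin_to_in, paths$pin_to_in)
  write_table(tb$ingredient_codes, paths$ingredient_codes)
  write_table(tb$code_classes, paths$code_classes)
  write_table(tb$ade_trees, paths$ade_trees)
  write_table(gen$truth$pair_truth, paths$truth)
  invisible(paths)
}
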