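# Shared fixtures: a small hand-built terminology and corpus modelled on the
# motivating pharmacology (fluoroquinolones, statins, SSRIs), plus
# independent brute-force oracles used to check the vectorized code paths.

toy_drug_vocab <- function() {
  drug_vocabulary(
    term_to_ingredient = data.frame(
      term_id = c("T_oflox", "T_cipro", "T_levo", "T_moxi",
                  "T_rosuva", "T_atorva", "T_simva",
                  "T_valproic_acid", "T_valproate", "T_orphan"),
      ingredient_id = c("oflox", "cipro", "levo", "moxi",
                        "rosuva", "atorva", "simva",
                        "PIN_valproate", "valproate", "orphan"),
      stringsAsFactors = FALSE),
    pin_to_in = data.frame(pin_ingredient_id = "PIN_valproate",
                           ingredient_id = "valproate",
                           stringsAsFactors = FALSE),
    ingredient_codes = data.frame(
      ingredient_id = c("oflox", "oflox", "cipro", "levo", "moxi",
                        "rosuva", "atorva", "simva", "valproate"),
      code_id = c("J01MA01", "S01AE01", "J01MA02", "J01MA12", "J01MA14",
                  "C10AA07", "C10AA05", "C10AA01", "N03AG01"),
      stringsAsFactors = FALSE),
    code_classes = data.frame(
      code_id = c("J01MA01", "S01AE01", "J01MA02", "J01MA12", "J01MA14",
                  "C10AA07", "C10AA05", "C10AA01", "N03AG01"),
      class_id = c("J01MA", "S01AE", "J01MA", "J01MA", "J01MA",
                   "C10AA", "C10AA", "C10AA", "N03AG"),
      class_name = c("Fluoroquinolones", "Fluoroquinolones (ophth.)",
                     "Fluoroquinolones", "Fluoroquinolones",
                     "Fluoroquinolones", "Statins", "Statins", "Statins",
                     "Fatty acid derivatives"),
      stringsAsFactors = FALSE))
}

toy_ade_vocab <- function() {
  ade_vocabulary(data.frame(
    term_id = c("muscular_diseases", "tendinopathy", "rhabdomyolysis",
                "liver_diseases", "dili", "headache_top"),
    tree_number = c("C05.651", "C05.651.869", "C05.651.807",
                    "C06.552", "C06.552.100", "C23"),
    stringsAsFactors = FALSE))
}

# article -> list of c(descriptor, qualifiers...)
toy_corpus <- function() {
  corpus(list(
    A1 = list(c("T_oflox", "AE"), c("tendinopathy", "CI")),
    A2 = list(c("T_oflox", "AE"), c("T_cipro", "AE"), c("tendinopathy", "CI"),
              c("rhabdomyolysis", "CI")),
    A3 = list(c("T_rosuva", "AE"), c("rhabdomyolysis", "CI"), c("D_noise")),
    A4 = list(c("T_simva", "AE"), c("dili")),
    A5 = list(c("T_cipro", "AE")),
    A6 = list(c("tendinopathy", "CI")),
    A7 = list(c("T_valproic_acid", "AE"), c("dili", "CI")),
    A8 = list()))
}

# independent per-article recount of drug/ADE mention sets (no vectorized
# machinery; mirrors the extraction rules by direct loops)
bf_article_sets <- function(corp, rules, dvocab, avocab) {
  ann <- corp$annotations
  out <- list()
  for (id in corp$article_ids) {
    rows <- ann[ann$article_id == id, , drop = FALSE]
    drugs <- character(); ades <- character()
    for (r in seq_len(nrow(rows))) {
      quals <- strsplit(rows$qualifiers[r], ",", fixed = TRUE)[[1L]]
      ing <- normalize_drug(dvocab, rows$descriptor_id[r])
      if (!is.na(ing) && any(quals %in% rules$drug_qualifiers))
        drugs <- union(drugs, ing)
      if (rows$descriptor_id[r] %in% ade_terms(avocab) &&
          (any(quals %in% rules$ade_qualifiers) ||
           rows$descriptor_id[r] %in% rules$inherent_ade_descriptors))
        ades <- union(ades, rows$descriptor_id[r])
    }
    out[[id]] <- list(drugs = drugs, ades = ades)
  }
  out
}

# brute-force 2x2 counter over article sets (row/col are id sets; class
# predicates are "any member present")
bf_table <- function(sets, row_ids, col_ids, ade_map = NULL) {
  a <- b <- cc <- d <- 0L
  for (s in sets) {
    if (length(s$drugs) == 0L || length(s$ades) == 0L) next
    ades <- s$ades
    if (!is.null(ade_map)) {
      cls <- unique(unlist(ade_map[ades], use.names = FALSE))
      ades <- cls
    }
    r <- any(s$drugs %in% row_ids)
    k <- any(ades %in% col_ids)
    if (r && k) a <- a + 1L else if (r) b <- b + 1L else
      if (k) cc <- cc + 1L else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# direct PRR arithmetic, including the +0.5 branch
bf_prr <- function(a, b, cc, d) {
  if (b == 0 || cc == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  unname((a / (a + b)) / (cc / (cc + d)))
}

# exhaustive minimum within-SS over ALL 2-partitions (not just interval
# splits) with both sides >= min_size
bf_best_partition_ss <- function(values, min_size = 2L) {
  n <- length(values)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    if (sum(sel) < min_size || sum(!sel) < min_size) next
    g1 <- values[sel]; g2 <- values[!sel]
    ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (ss < best) best <- ss
  }
  best
}

within_ss <- function(values, assignment) {
  sum(vapply(split(values, assignment),
             function(g) sum((g - mean(g))^2), numeric(1)))
}

# closed-form Welch statistic, written independently of stats::t.test
bf_welch <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1L)
  vy <- sum((y - mean(y))^2) / (length(y) - 1L)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  dof <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1L)) +
                    vy^2 / (length(y)^2 * (length(y) - 1L)))
  p <- 2 * stats::pt(-abs(t), dof)
  list(t = t, dof = dof, p = p)
}

# naive complete-linkage agglomeration; returns merge heights and the leaf
# partition after each merge (order-free summaries for comparison)
bf_complete_linkage <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bh)
    partitions[[length(partitions) + 1L]] <- canon_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (sorted list of sorted member vectors)
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(sapply(p, `[`, 1L))]
}

# partition of leaves implied by an hclust-style merge matrix after m merges
merge_partition <- function(merge, n, m) {
  node <- vector("list", m)
  consumed_leaf <- logical(n)
  consumed_node <- logical(max(m, 1L))
  for (k in seq_len(m)) {
    get <- function(v) {
      if (v < 0) { consumed_leaf[-v] <<- TRUE; -v }
      else { consumed_node[v] <<- TRUE; node[[v]] }
    }
    node[[k]] <- sort(c(get(merge[k, 1L]), get(merge[k, 2L])))
  }
  live <- if (m > 0L) node[!consumed_node[seq_len(m)]] else list()
  canon_partition(c(live, as.list(which(!consumed_leaf))))
}
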