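#' Pairs eligible for class-effect determination
#'
#' A (drug class, ADE) pair can only be judged when every member of the
#' class has literature evidence for that ADE: if some members have no
#' co-occurrence at all, absence of evidence cannot be distinguished from
#' evidence of absence, and the pair is excluded. The class-size filter
#' (at least four members) is assumed to have been applied upstream via
#' \code{\link{eligible_classes}}.
#'
#' @param class_members named list: class id -> member ingredient ids
#' @param drug_records drug-level signal records (rows are ingredients,
#'   columns the ADE resolution of interest) from \code{\link{signal_scan}}
#' @return data.frame with columns \code{class_id}, \code{ade_id}
#' @export
eligible_pairs <- function(class_members, drug_records) {
  stopifnot(is.list(class_members))
  out <- lapply(names(class_members), function(cl) {
    members <- class_members[[cl]]
    sub <- drug_records[drug_records$row_id %in% members, ]
    if (nrow(sub) == 0L) return(NULL)
    cover <- tapply(sub$row_id, sub$col_id,
                    function(r) length(unique(r)))
    ades <- names(cover)[cover == length(members)]
    if (length(ades) == 0L) return(NULL)
    data.frame(class_id = cl, ade_id = sort(ades), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(class_id = character(), ade_id = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Optimal two-cluster partition of one-dimensional values
#'
#' Deterministic 1-D two-means: values are sorted and every contiguous
#' split with both sides holding at least \code{min_cluster_size} values is
#' scored by total within-cluster sum of squared deviations; the minimizing
#' split is returned. For one-dimensional data the optimal two-means
#' partition is always an interval split, so this equals exhaustive search
#' over all two-partitions under the size constraint. The size constraint
#' (default 2) guarantees both clusters support a variance estimate for the
#' downstream Welch test. Fewer than two distinct values yield a single
#' cluster, read as homogeneous by design.
#'
#' @param values numeric vector (log-PRRs of the class members)
#' @param min_cluster_size minimum size of each cluster (default 2)
#' @return list with \code{n_clusters} (1 or 2), \code{assignment} (integer
#'   vector aligned with \code{values}; 1 = lower cluster, 2 = upper
#'   cluster, all 1 when a single cluster), and \code{degenerate} (TRUE
#'   when there were too few values to attempt a split)
#' @export
split_two <- function(values, min_cluster_size = 2L) {
  stopifnot(is.numeric(values), !anyNA(values), min_cluster_size >= 1L)
  n <- length(values)
  one <- function(degenerate = FALSE)
    list(n_clusters = 1L, assignment = rep(1L, n), degenerate = degenerate)
  if (n < 2L * min_cluster_size) return(one(degenerate = TRUE))
  if (length(unique(values)) < 2L) return(one())
  ord <- order(values)
  s <- values[ord]
  # prefix sums give within-SS of every interval in O(1)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  tot <- cs[n]; tot2 <- cs2[n]
  ks <- seq.int(min_cluster_size, n - min_cluster_size)
  ss_left <- cs2[ks] - cs[ks]^2 / ks
  ss_right <- (tot2 - cs2[ks]) - (tot - cs[ks])^2 / (n - ks)
  k <- ks[which.min(ss_left + ss_right)]
  assignment <- integer(n)
  assignment[ord] <- ifelse(seq_len(n) <= k, 1L, 2L)
  list(n_clusters = 2L, assignment = assignment, degenerate = FALSE)
}

#' Welch's two-sample t-test
#'
#' Two-sided comparison of group means with the Welch-Satterthwaite
#' degrees of freedom, tolerating unequal variances. When both groups have
#' zero variance the statistic is undefined; the test then degenerates to
#' p = 1 for equal means and p = 0 otherwise.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2
#' @return list with \code{t_stat}, \code{dof}, \code{p_value}
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("both groups need at least 2 values")
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    same <- mean(group_a) == mean(group_b)
    return(list(t_stat = if (same) 0 else
      sign(mean(group_a) - mean(group_b)) * Inf,
      dof = NA_real_, p_value = if (same) 1 else 0))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t_stat = unname(fit$statistic), dof = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Classify one (drug class, ADE) pair as class effect or not
#'
#' Partitions the members' log-PRRs into two clusters with
#' \code{\link{split_two}} and compares the cluster means with Welch's
#' t-test. A single cluster, or two clusters whose means do not differ
#' significantly (p > alpha), indicates that all members contribute to the
#' class signal — a class effect. Two significantly different clusters mean
#' the signal is driven by a subset of members — heterogeneous.
#'
#' @param class_id,ade_id identifiers of the pair
#' @param member_log_prrs named numeric vector: member ingredient ->
#'   natural-log PRR for this ADE
#' @param alpha significance level of the Welch test (default 0.05)
#' @param min_cluster_size minimum cluster size for the split (default 2)
#' @param method \code{"optimal"} for the deterministic interval split;
#'   \code{"kmeans"} for Lloyd-style k-means (random initialization,
#'   comparison mode; set a seed for reproducibility)
#' @return an object of class \code{classfx_class_effect}
#' @export
classify_pair <- function(class_id, ade_id, member_log_prrs, alpha = 0.05,
                          min_cluster_size = 2L,
                          method = c("optimal", "kmeans")) {
  stopifnot(is.numeric(member_log_prrs), length(member_log_prrs) >= 1L)
  method <- match.arg(method)
  values <- unname(member_log_prrs)
  members <- names(member_log_prrs)
  if (is.null(members)) members <- paste0("m", seq_along(values))
  if (method == "optimal") {
    sp <- split_two(values, min_cluster_size = min_cluster_size)
  } else {
    sp <- kmeans_split(values)
  }
  if (sp$n_clusters == 1L) {
    res <- list(class_id = class_id, ade_id = ade_id,
                member_log_prrs = setNames(values, members),
                n_clusters = 1L,
                partition = list(members, character()),
                cluster_means = c(mean(values), NA_real_),
                t_stat = NA_real_, dof = NA_real_, p_value = NA_real_,
                alpha = alpha, degenerate = isTRUE(sp$degenerate),
                verdict = "class_effect_single_cluster")
    return(structure(res, class = "classfx_class_effect"))
  }
  g1 <- values[sp$assignment == 1L]
  g2 <- values[sp$assignment == 2L]
  test <- welch_test(g1, g2)
  verdict <- if (test$p_value > alpha) "class_effect_homogeneous" else
    "heterogeneous"
  res <- list(class_id = class_id, ade_id = ade_id,
              member_log_prrs = setNames(values, members),
              n_clusters = 2L,
              partition = list(members[sp$assignment == 1L],
                               members[sp$assignment == 2L]),
              cluster_means = c(mean(g1), mean(g2)),
              t_stat = test$t_stat, dof = test$dof, p_value = test$p_value,
              alpha = alpha, degenerate = FALSE, verdict = verdict)
  structure(res, class = "classfx_class_effect")
}

# Lloyd k-means (k = 2) on scalars, for comparison with the deterministic
# split; may return singleton clusters, which classify_pair folds into the
# single-cluster verdict because no variance estimate exists.
kmeans_split <- function(values) {
  n <- length(values)
  if (n < 2L || length(unique(values)) < 2L)
    return(list(n_clusters = 1L, assignment = rep(1L, n), degenerate = n < 4L))
  km <- stats::kmeans(values, centers = 2L)
  lower <- which.min(km$centers)
  assignment <- ifelse(km$cluster == lower, 1L, 2L)
  if (min(table(assignment)) < 2L)
    return(list(n_clusters = 1L, assignment = rep(1L, n), degenerate = FALSE))
  list(n_clusters = 2L, assignment = assignment, degenerate = FALSE)
}

#' @export
print.classfx_class_effect <- function(x, ...) {
  cat("<classfx_class_effect> ", x$class_id, " ~ ", x$ade_id, "\n", sep = "")
  cat("  members: ", paste(sprintf("%s=%.3f", names(x$member_log_prrs),
                                   x$member_log_prrs), collapse = ", "),
      "\n", sep = "")
  if (x$n_clusters == 2L) {
    cat(sprintf("  clusters: {%s} | {%s}\n",
                paste(x$partition[[1L]], collapse = ", "),
                paste(x$partition[[2L]], collapse = ", ")))
    cat(sprintf("  Welch t = %.3f, dof = %.2f, p = %.4f (alpha = %g)\n",
                x$t_stat, x$dof, x$p_value, x$alpha))
  } else {
    cat("  single cluster\n")
  }
  cat("  verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Class-effect scan over all eligible pairs
#'
#' Applies \code{\link{classify_pair}} to every eligible (class, ADE) pair,
#' drawing member log-PRRs from the drug-level records and attaching the
#' class-level PRR when class-level records are supplied. No
#' multiple-testing correction is applied across the scan; each pair is
#' tested at \code{alpha} (recorded in the \code{alpha} attribute together
#' with a \code{multiplicity} note).
#'
#' @param eligible data.frame (class_id, ade_id) from
#'   \code{\link{eligible_pairs}}
#' @param drug_records drug-level signal records
#' @param class_members named list: class id -> member ingredient ids
#' @param class_records optional class-level signal records (same column
#'   resolution)
#' @param alpha significance level (default 0.05)
#' @param min_cluster_size minimum cluster size (default 2)
#' @return data.frame with one row per eligible pair: identifiers, member
#'   count, clustering summary, Welch statistics, verdict, and class-level
#'   log-PRR when available
#' @export
class_effect_scan <- function(eligible, drug_records, class_members,
                              class_records = NULL, alpha = 0.05,
                              min_cluster_size = 2L) {
  n <- nrow(eligible)
  rows <- vector("list", n)
  key <- paste(drug_records$row_id, drug_records$col_id, sep = "\r")
  lp <- setNames(drug_records$log_prr, key)
  class_lp <- if (!is.null(class_records))
    setNames(class_records$log_prr,
             paste(class_records$row_id, class_records$col_id, sep = "\r"))
  for (i in seq_len(n)) {
    cl <- eligible$class_id[i]
    ade <- eligible$ade_id[i]
    members <- class_members[[cl]]
    v <- lp[paste(members, ade, sep = "\r")]
    if (anyNA(v))
      stop("pair (", cl, ", ", ade, ") is not eligible: member without data")
    res <- classify_pair(cl, ade, setNames(unname(v), members), alpha = alpha,
                         min_cluster_size = min_cluster_size)
    rows[[i]] <- data.frame(
      class_id = cl, ade_id = ade, n_members = length(members),
      n_clusters = res$n_clusters,
      cluster_mean_low = res$cluster_means[1L],
      cluster_mean_high = res$cluster_means[2L],
      t_stat = res$t_stat, dof = res$dof, p_value = res$p_value,
      verdict = res$verdict,
      class_log_prr = if (!is.null(class_records))
        unname(class_lp[paste(cl, ade, sep = "\r")]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class_id = character(), ade_id = character(),
                      n_members = integer(), n_clusters = integer(),
                      cluster_mean_low = numeric(),
                      cluster_mean_high = numeric(), t_stat = numeric(),
                      dof = numeric(), p_value = numeric(),
                      verdict = character(), class_log_prr = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "multiplicity") <- "none (each pair tested at alpha)"
  out
}
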