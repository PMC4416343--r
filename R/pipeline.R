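#' Run configuration for the full pipeline
#'
#' Collects the input paths, rule sets and thresholds of one reproducible
#' run. All referenced inputs must exist before any computation starts.
#'
#' @param corpus path to a JSON-lines citation file
#' @param drug_terms,pin_to_in,ingredient_codes,code_classes,ade_trees paths
#'   to the terminology TSV tables (\code{pin_to_in} optional)
#' @param out_dir output directory (created if missing)
#' @param drug_qualifiers,ade_qualifiers,inherent_ade_descriptors extraction
#'   rules (see \code{\link{extraction_rules}})
#' @param min_members minimum observed class size (default 4)
#' @param alpha significance level for the class-effect test (default 0.05)
#' @param levels signal resolutions to compute and write (default all four)
#' @param heatmap_classes drug classes to drill into with level-2 heat maps;
#'   \code{NULL} for none, \code{"all"} for every eligible class
#' @param render_png also render PNG images for the exported heat maps
#' @return an object of class \code{classfx_run_config}
#' @export
run_config <- function(corpus, drug_terms, ingredient_codes, code_classes,
                       ade_trees, out_dir, pin_to_in = NULL,
                       drug_qualifiers = "AE", ade_qualifiers = "CI",
                       inherent_ade_descriptors = character(),
                       min_members = 4L, alpha = 0.05,
                       levels = signal_levels, heatmap_classes = "all",
                       render_png = FALSE) {
  cfg <- list(corpus = corpus, drug_terms = drug_terms,
              pin_to_in = pin_to_in, ingredient_codes = ingredient_codes,
              code_classes = code_classes, ade_trees = ade_trees,
              out_dir = out_dir, drug_qualifiers = drug_qualifiers,
              ade_qualifiers = ade_qualifiers,
              inherent_ade_descriptors = inherent_ade_descriptors,
              min_members = as.integer(min_members), alpha = alpha,
              levels = match.arg(levels, signal_levels, several.ok = TRUE),
              heatmap_classes = heatmap_classes, render_png = render_png)
  inputs <- c(cfg$corpus, cfg$drug_terms, cfg$pin_to_in,
              cfg$ingredient_codes, cfg$code_classes, cfg$ade_trees)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  structure(cfg, class = "classfx_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Paths in the file are resolved relative to the file's directory.
#'
#' @param path YAML file with the fields of \code{\link{run_config}}
#' @return a \code{classfx_run_config}
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML run configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (f in c("corpus", "drug_terms", "pin_to_in", "ingredient_codes",
              "code_classes", "ade_trees", "out_dir"))
    if (!is.null(raw[[f]])) raw[[f]] <- rel(raw[[f]])
  do.call(run_config, raw)
}

#' Run the full pipeline: extract, signal, class effect, heat maps
#'
#' One reproducible end-to-end run. Writes to \code{out_dir}: the
#' article-level drug-ADE pair table, a signal table per requested
#' resolution, the class-effect verdict table, the clustered class-level
#' heat-map matrix plus a drug-level drill-down matrix per selected class,
#' and a JSON manifest recording input digests, the configuration, the
#' package version and the record count at every stage.
#'
#' @param config a \code{classfx_run_config} or path to a YAML file
#' @return the manifest, invisibly (a named list)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "classfx_run_config"))
  stage <- "setup"
  out <- tryCatch({
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)

    stage <- "load"
    corpus <- read_corpus(config$corpus)
    drug_vocab <- read_drug_vocabulary(config$drug_terms, config$pin_to_in,
                                       config$ingredient_codes,
                                       config$code_classes)
    ade_vocab <- read_ade_vocabulary(config$ade_trees)
    rules <- extraction_rules(config$drug_qualifiers, config$ade_qualifiers,
                              config$inherent_ade_descriptors)

    stage <- "extract"
    mentions <- extract_mentions(corpus, rules, drug_vocab, ade_vocab)
    pairs <- extract_pairs(mentions)
    write_table(pairs, file.path(config$out_dir, "pairs.tsv"))

    stage <- "signal"
    universe <- build_universe(mentions)
    members <- eligible_classes(universe$ingredients, drug_vocab,
                                min_members = config$min_members)
    signals <- list()
    for (lv in config$levels) {
      signals[[lv]] <- signal_scan(universe, lv, ade_vocab = ade_vocab,
                                   class_members = members)
      write_table(signals[[lv]],
                  file.path(config$out_dir, paste0("signals_", lv, ".tsv")))
    }

    stage <- "class_effect"
    drug_recs <- signals[["drug_x_ade_class"]]
    if (is.null(drug_recs))
      drug_recs <- signal_scan(universe, "drug_x_ade_class",
                               ade_vocab = ade_vocab)
    class_recs <- signals[["class_x_ade_class"]]
    if (is.null(class_recs))
      class_recs <- signal_scan(universe, "class_x_ade_class",
                                ade_vocab = ade_vocab, class_members = members)
    eligible <- eligible_pairs(members, drug_recs)
    verdicts <- class_effect_scan(eligible, drug_recs, members,
                                  class_records = class_recs,
                                  alpha = config$alpha)
    write_table(verdicts, file.path(config$out_dir, "verdicts.tsv"))

    stage <- "heatmap"
    heatmap_files <- character()
    if (nrow(class_recs) > 0L) {
      hm <- build_heatmap(class_recs)
      f <- file.path(config$out_dir, "heatmap_class_x_ade_class.tsv")
      export_heatmap(hm, f)
      if (config$render_png) render_heatmap(hm, sub("\\.tsv$", ".png", f))
      heatmap_files <- c(heatmap_files, f)
    }
    drill <- config$heatmap_classes
    if (!is.null(drill)) {
      if (identical(drill, "all")) drill <- names(members)
      for (cl in intersect(drill, names(members))) {
        sub <- drug_recs[drug_recs$row_id %in% members[[cl]], ]
        if (nrow(sub) == 0L) next
        hm <- build_heatmap(drug_recs, rows = members[[cl]])
        f <- file.path(config$out_dir, paste0("heatmap_drug_x_ade_class_",
                                              cl, ".tsv"))
        export_heatmap(hm, f)
        if (config$render_png) render_heatmap(hm, sub("\\.tsv$", ".png", f))
        heatmap_files <- c(heatmap_files, f)
      }
    }

    stage <- "manifest"
    inputs <- c(corpus = config$corpus, drug_terms = config$drug_terms,
                pin_to_in = config$pin_to_in,
                ingredient_codes = config$ingredient_codes,
                code_classes = config$code_classes,
                ade_trees = config$ade_trees)
    manifest <- list(
      tool = "classfx",
      version = as.character(utils::packageVersion("classfx")),
      config = unclass(config),
      input_md5 = as.list(tools::md5sum(inputs)),
      counts = list(
        articles = length(corpus$article_ids),
        universe_articles = length(universe$article_ids),
        pair_rows = nrow(pairs),
        ingredients = length(universe$ingredients),
        ade_terms = length(universe$ade_terms),
        eligible_classes = length(members),
        eligible_pairs = nrow(eligible),
        verdicts = as.list(table(verdicts$verdict))),
      outputs = c(file.path(config$out_dir, "pairs.tsv"),
                  file.path(config$out_dir,
                            paste0("signals_", config$levels, ".tsv")),
                  file.path(config$out_dir, "verdicts.tsv"), heatmap_files))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}
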