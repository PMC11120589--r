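#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Every stochastic stage
#' derives its seed from the single `seed` field, so two runs with the
#' same configuration produce byte-identical outputs.
#'
#' @param input `"table1"`, a CSV path, or an `od_design` object.
#' @param directions criterion directions for the scoring stage.
#' @param k flat cluster count for the clustering stage.
#' @param ann logical; run the (slow) perceptron modeling stage.
#' @param ann_config a [train_config()] for the modeling stage; its seed
#'   is overridden by `seed`.
#' @param out_dir output directory (created if absent).
#' @param seed master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = "table1",
                            directions = default_directions(),
                            k = 4L, ann = FALSE,
                            ann_config = train_config(),
                            out_dir = tempfile("osmodry_out_"),
                            seed = 1L) {
  if (!(is.character(input) || inherits(input, "od_design"))) {
    stop("config field 'input' must be a builtin name, a path, or an od_design")
  }
  if (!all(directions %in% c("benefit", "cost")) || is.null(names(directions))) {
    stop("config field 'directions' must be a named benefit/cost vector")
  }
  if (!is.numeric(k) || k < 1) stop("config field 'k' must be a positive integer")
  if (!is.logical(ann)) stop("config field 'ann' must be logical")
  if (!inherits(ann_config, "train_config")) {
    stop("config field 'ann_config' must be a train_config")
  }
  if (!is.numeric(seed)) stop("config field 'seed' must be an integer")
  structure(list(input = input, directions = directions, k = as.integer(k),
                 ann = ann, ann_config = ann_config, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `input`, `directions` (name -> benefit/cost map),
#' `k`, `ann`, `out_dir`, `seed`, and `ann_config` with `hidden` (vector
#' or "lo:hi" string), `restarts`, `maxit`, `f_hidden`, `f_output`.
#'
#' @param path YAML file.
#' @return A validated [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("input", "k", "ann", "out_dir", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$directions)) {
    args$directions <- unlist(y$directions)
  }
  if (!is.null(y$ann_config)) {
    ac <- y$ann_config
    if (is.character(ac$hidden)) {
      rng <- as.integer(strsplit(ac$hidden, ":", fixed = TRUE)[[1]])
      ac$hidden <- seq(rng[1], rng[2])
    }
    args$ann_config <- do.call(train_config, ac)
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Orchestrates load -> scoring -> correlation -> clustering -> PCA
#' (-> perceptron modeling -> fit report -> sensitivity) and writes the
#' stage outputs to `cfg$out_dir`: `scores.csv`, `correlations.csv`,
#' `clusters.json`, `pca.csv`, and with `ann = TRUE` also
#' `ann_models.json`, `fit_report.csv` and `ri_matrix.csv`, plus a
#' `summary.json` naming the optimal run and its response values. A
#' stage failure aborts with the stage name and removes partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(input = "table1"))
#' res$summary$optimal_run
#' }
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- function(name, expr) {
    message(sprintf("[osmodry seed=%d] stage: %s", cfg$seed, name))
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(file) {
    path <- file.path(cfg$out_dir, file)
    written <<- c(written, path)
    path
  }

  table <- stage("load", {
    if (inherits(cfg$input, "od_design")) cfg$input else load_design_table(cfg$input)
  })
  scores <- stage("scoring", {
    sc <- standard_scores(table, cfg$directions)
    utils::write.csv(as.data.frame(sc), emit("scores.csv"), row.names = FALSE)
    sc
  })
  correlations <- stage("correlation", {
    ct <- pearson_matrix(table)
    utils::write.csv(ct$r, emit("correlations.csv"))
    ct
  })
  clusters <- stage("clustering", {
    cl <- cluster_runs(table, k = cfg$k)
    jsonlite::write_json(
      list(metric = cl$metric, linkage = cl$linkage, k = cl$k,
           heights = cl$heights, members = cl$members),
      emit("clusters.json"), digits = NA, auto_unbox = TRUE)
    cl
  })
  pca <- stage("pca", {
    p <- pca_correlation(table)
    utils::write.csv(
      data.frame(component = colnames(p$loadings),
                 eigenvalue = p$eigenvalues,
                 percent_variance = p$percent_variance,
                 t(p$loadings)),
      emit("pca.csv"), row.names = FALSE)
    p
  })

  fits <- report <- ri <- NULL
  if (cfg$ann) {
    fits <- stage("ann", {
      ac <- cfg$ann_config
      ac$seed <- cfg$seed
      fs <- topology_search(table, cfg = ac)
      models_to_json(fs, emit("ann_models.json"))
      fs
    })
    report <- stage("fit_report", {
      fr <- suppressWarnings(fit_report(fits, table))
      utils::write.csv(fr, emit("fit_report.csv"), row.names = FALSE)
      fr
    })
    ri <- stage("sensitivity", {
      m <- ri_matrix(fits)
      utils::write.csv(m, emit("ri_matrix.csv"))
      m
    })
  }

  summary_out <- stage("summary", {
    best <- scores[scores$rank == 1L, ]
    run_row <- as.data.frame(table)[table$run == best$run, ]
    s <- list(optimal_run = best$run,
              SS = best$SS,
              factors = as.list(run_row[, od_factor_names()]),
              responses = as.list(run_row[, intersect(od_response_names(),
                                                      names(run_row))]),
              seed = cfg$seed)
    jsonlite::write_json(s, emit("summary.json"), digits = NA, auto_unbox = TRUE)
    s
  })

  invisible(list(table = table, scores = scores, correlations = correlations,
                 clusters = clusters, pca = pca, fits = fits,
                 fit_report = report, ri = ri, summary = summary_out,
                 files = written))
}
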