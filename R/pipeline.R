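# End-to-end orchestration: normalize -> cluster -> order -> test, with
# tables written first and every figure re-rendered from the saved tables,
# so any visual can be regenerated post hoc from the bundle alone.

#' Pipeline configuration
#'
#' Exactly one input source must be given: either `input_paths` (chip CSV
#' exports, one per passage group, read with [read_chip_table()]) or
#' `synthetic` (a [cohort_spec()] to simulate).
#'
#' @param input_paths Named character vector of chip CSV paths; names are
#'   the passage labels.
#' @param synthetic A `SyntheticCohortSpec`.
#' @param panel Gene panel for file input (default [default_gene_panel()]).
#' @param cycle_limit Cycle limit for file input (default 40).
#' @param clip_bound Normalization clip bound (default 5).
#' @param k Cluster count, or `"auto"` for silhouette-guided selection.
#' @param k_min,k_max Candidate range when `k = "auto"`.
#' @param n_restarts k-means restarts (default 50).
#' @param alpha Family-wise significance level (default 0.05; use 0.01 for
#'   the stricter preset).
#' @param include_nonexpressers Include floored non-expressers in K-S
#'   samples (default `TRUE`).
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory for the report bundle.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(input_paths = NULL, synthetic = NULL,
                            panel = default_gene_panel(),
                            cycle_limit = 40L, clip_bound = 5,
                            k = "auto", k_min = 2L, k_max = 8L,
                            n_restarts = 50L, alpha = 0.05,
                            include_nonexpressers = TRUE,
                            seed = 1L, out_dir = "scqpcr_report") {
  if (is.null(input_paths) == is.null(synthetic)) {
    stop("provide exactly one of `input_paths` or `synthetic`",
         call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "SyntheticCohortSpec"))
  if (!is.null(input_paths) && is.null(names(input_paths))) {
    stop("`input_paths` must be named by passage label", call. = FALSE)
  }
  if (!identical(k, "auto")) k <- .assert_count(k, "k")
  structure(
    list(input_paths = input_paths, synthetic = synthetic,
         panel = as.character(panel), cycle_limit = cycle_limit,
         clip_bound = clip_bound, k = k, k_min = k_min, k_max = k_max,
         n_restarts = n_restarts, alpha = alpha,
         include_nonexpressers = include_nonexpressers,
         seed = seed, out_dir = out_dir),
    class = "PipelineConfig"
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: acquire (read chips or simulate) -> pool and normalize ->
#' cluster (with optional silhouette-guided cluster-count selection) ->
#' hierarchical ordering -> composition -> K-S contrasts (cluster-vs-rest
#' and passage pairs) -> figures. Writes, under `cfg$out_dir`:
#' `normalized.tsv`, `mask.tsv`, `clusters.tsv`, `composition.tsv`,
#' `ks_results.tsv`, `clustergram.png`, `composition_pie.png`,
#' `manifest.json`, `run_log.txt`. Deterministic given the config seed: two
#' runs with the same config produce byte-identical tables, and the
#' manifest alone suffices to replay the run (see [replay_pipeline()]).
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  if (!is.null(cfg$synthetic)) {
    cohort <- .stage("simulate", generate_cohort(cfg$synthetic))
    m <- cohort$matrix
    note("simulate: ", nrow(m$ct), " cells x ", length(m$genes), " genes")
  } else {
    runs <- .stage("read", lapply(names(cfg$input_paths), function(p) {
      read_chip_table(cfg$input_paths[[p]], gene_panel(cfg$panel),
                      passage = p, cycle_limit = cfg$cycle_limit)
    }))
    m <- .stage("merge", merge_runs(runs))
    note("read+merge: ", nrow(m$ct), " cells x ", length(m$genes),
         " genes from ", length(runs), " chip(s)")
  }

  x <- .stage("normalize", normalize_to_median(m, cfg$clip_bound))
  note("normalize: clip bound +/-", cfg$clip_bound,
       "; floored positions ", sum(!x$expresser))

  if (identical(cfg$k, "auto")) {
    k_sel <- .stage("select_k", select_cluster_count(
      x, k_min = cfg$k_min, k_max = cfg$k_max,
      n_restarts = cfg$n_restarts, seed = cfg$seed))
    model <- attr(k_sel, "models")[[as.character(as.integer(k_sel))]]
    sil <- attr(k_sel, "silhouette")
    k_used <- as.integer(k_sel)
    note("select_k: k = ", k_used, " (mean silhouette ",
         sprintf("%.4f", sil[[as.character(k_used)]]), ")")
  } else {
    model <- .stage("cluster", fit_kmeans(
      x, cfg$k, n_restarts = cfg$n_restarts,
      seed = .mix_seed(cfg$seed, 31L, cfg$k)))
    sil <- NULL
    k_used <- cfg$k
    note("cluster: fixed k = ", k_used)
  }
  note("cluster sizes: ",
       paste(tabulate(model$assignments, model$k), collapse = ", "),
       "; WCSS = ", sprintf("%.4f", model$wcss))

  ord <- .stage("order", order_hierarchically(x, model))
  comp <- .stage("composition", composition(model, x$cells$passage))

  ks <- .stage("test", {
    cvr <- cluster_vs_rest(x, model, alpha = cfg$alpha,
                           include_nonexpressers = cfg$include_nonexpressers)
    cvr <- cbind(contrast = sprintf("cluster%d_vs_rest", cvr$cluster),
                 cvr[, setdiff(names(cvr), "cluster")])
    pc <- tryCatch(
      passage_contrasts(x, alpha = cfg$alpha,
                        include_nonexpressers = cfg$include_nonexpressers),
      error = function(e) NULL)
    rbind(cvr, pc)
  })
  sig_counts <- tapply(ks$significant, ks$contrast, sum)
  note("test: significant genes per contrast: ",
       paste(sprintf("%s=%d", names(sig_counts), sig_counts),
             collapse = ", "))

  # tables first; figures below are rendered from these files only
  paths <- list(
    normalized = .write_tsv(
      cbind(x$cells[, c("cell_id", "passage")],
            as.data.frame(x$values, check.names = FALSE)),
      file.path(cfg$out_dir, "normalized.tsv")),
    mask = .write_tsv(
      cbind(x$cells[, c("cell_id", "passage")],
            as.data.frame(x$expresser, check.names = FALSE)),
      file.path(cfg$out_dir, "mask.tsv")),
    clusters = .write_tsv(
      data.frame(cell_id = x$cells$cell_id, passage = x$cells$passage,
                 cluster = model$assignments,
                 order = order(ord$cell_order)),
      file.path(cfg$out_dir, "clusters.tsv")),
    composition = .write_tsv(comp, file.path(cfg$out_dir, "composition.tsv")),
    ks = .write_tsv(ks, file.path(cfg$out_dir, "ks_results.tsv"))
  )

  manifest <- list(
    package = "scqpcr",
    version = as.character(utils::packageVersion("scqpcr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = .config_to_list(cfg),
    k_selected = k_used,
    silhouette_by_k = as.list(sil),
    n_cells = nrow(x$values), n_genes = length(x$genes),
    significant_genes = as.list(sig_counts),
    tables = vapply(paths, basename, character(1L))
  )
  # digits = I(17): significant digits, enough for a bit-exact double
  # round-trip so a replayed run reproduces every table byte for byte
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  fig <- render_report(cfg$out_dir, clip_bound = cfg$clip_bound)

  invisible(list(matrix = m, normalized = x, model = model, order = ord,
                 composition = comp, ks = ks, k_selected = k_used,
                 paths = c(paths, fig),
                 manifest_path = file.path(cfg$out_dir, "manifest.json")))
}

.config_to_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$synthetic)) {
    s <- unclass(out$synthetic)
    s$shift_matrix <- apply(s$shift_matrix, 1L, identity, simplify = FALSE)
    s$mixing_rows <- rownames(out$synthetic$mixing)
    s$mixing <- apply(s$mixing, 1L, identity, simplify = FALSE)
    out$synthetic <- s
  }
  out
}

.config_from_list <- function(lst) {
  # jsonlite renders a dropped-NULL slot as an empty container
  if (length(lst$input_paths) == 0L) lst$input_paths <- NULL
  if (length(lst$synthetic) == 0L) lst$synthetic <- NULL
  syn <- NULL
  if (!is.null(lst$synthetic)) {
    s <- lst$synthetic
    mixing <- do.call(rbind, lapply(s$mixing, unlist))
    rownames(mixing) <- unlist(s$mixing_rows)
    syn <- cohort_spec(
      n_genes = s$n_genes, k_true = s$k_true,
      baseline_ct = unlist(s$baseline_ct), within_sd = s$within_sd,
      shift_matrix = do.call(rbind, lapply(s$shift_matrix, unlist)),
      mixing = mixing, cells_per_group = s$cells_per_group,
      dropout_base = s$dropout_base, dropout_slope = s$dropout_slope,
      ct0 = s$ct0, dropout_cap = s$dropout_cap,
      cycle_limit = s$cycle_limit, seed = s$seed)
  }
  pipeline_config(
    input_paths = if (!is.null(lst$input_paths))
      stats::setNames(unlist(lst$input_paths), names(lst$input_paths)),
    synthetic = syn,
    panel = unlist(lst$panel), cycle_limit = lst$cycle_limit,
    clip_bound = lst$clip_bound,
    k = if (identical(lst$k, "auto")) "auto" else as.integer(lst$k),
    k_min = lst$k_min, k_max = lst$k_max, n_restarts = lst$n_restarts,
    alpha = lst$alpha,
    include_nonexpressers = lst$include_nonexpressers,
    seed = lst$seed, out_dir = lst$out_dir)
}

#' Replay a pipeline run from its manifest
#'
#' Reconstructs the configuration recorded in a `manifest.json` and reruns
#' the pipeline, optionally into a different directory. With the same seed
#' the replay reproduces every table byte for byte.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Optional new output directory (default: the one recorded).
#' @return As [run_pipeline()].
#' @export
replay_pipeline <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path)
  cfg <- .config_from_list(man$config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(cfg)
}

#' Render report figures from saved tables
#'
#' Reads `normalized.tsv`, `mask.tsv`, `clusters.tsv` and `composition.tsv`
#' from a report directory and renders the clustergram and the per-cluster
#' passage-composition pies. Figures are always derived from the saved
#' tables, never from in-memory state, so they can be regenerated at any
#' time.
#'
#' @param dir Report directory written by [run_pipeline()].
#' @param clip_bound Color-scale bound in log2 units (default 5 = 32-fold).
#' @return Named list of figure paths.
#' @export
render_report <- function(dir, clip_bound = 5) {
  norm <- utils::read.delim(file.path(dir, "normalized.tsv"),
                            check.names = FALSE)
  mask <- utils::read.delim(file.path(dir, "mask.tsv"), check.names = FALSE)
  clus <- utils::read.delim(file.path(dir, "clusters.tsv"))
  comp <- utils::read.delim(file.path(dir, "composition.tsv"))
  v <- as.matrix(norm[, -(1:2), drop = FALSE])
  rownames(v) <- norm$cell_id
  e <- as.matrix(mask[, -(1:2), drop = FALSE]) == "TRUE" |
    as.matrix(mask[, -(1:2), drop = FALSE]) == TRUE
  cg <- file.path(dir, "clustergram.png")
  pie <- file.path(dir, "composition_pie.png")
  .render_clustergram_tables(v, e, clus, clip_bound, cg)
  .render_composition_pies(comp, pie)
  list(clustergram = cg, composition_pie = pie)
}

.render_clustergram_tables <- function(values, expresser, clusters,
                                       clip_bound, file) {
  ord <- order(clusters$cluster, clusters$order)
  v <- values[ord, , drop = FALSE]
  v[!expresser[ord, , drop = FALSE]] <- NA   # grey in the heatmap
  gaps <- cumsum(table(sort(clusters$cluster)))
  pheatmap::pheatmap(
    v,
    cluster_rows = FALSE, cluster_cols = FALSE,
    color = grDevices::colorRampPalette(c("blue", "black", "yellow"))(101),
    breaks = seq(-clip_bound, clip_bound, length.out = 102),
    na_col = "grey70",
    gaps_row = utils::head(as.integer(gaps), -1L),
    show_rownames = FALSE,
    border_color = NA,
    main = sprintf("log2 fold change vs median (+/-%g = %g-fold); grey = no amplification",
                   clip_bound, 2^clip_bound),
    filename = file, width = 8, height = 8, silent = TRUE
  )
  file
}

.render_composition_pies <- function(comp, file) {
  clusters <- sort(unique(comp$cluster))
  grDevices::png(file, width = 300 * length(clusters), height = 320,
                 res = 96)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, length(clusters)), mar = c(1, 1, 3, 1))
  shades <- c(fresh = "grey10", P0 = "grey50", P1 = "grey85")
  for (cl in clusters) {
    sub <- comp[comp$cluster == cl & comp$n > 0, , drop = FALSE]
    cols <- shades[as.character(sub$passage)]
    cols[is.na(cols)] <- "tomato"
    graphics::pie(sub$n, labels = sprintf("%s (%d)", sub$passage, sub$n),
                  col = cols, main = sprintf("cluster %d", cl))
  }
  file
}

#' Render a clustergram from in-memory objects
#'
#' Convenience wrapper around the table-driven renderer for interactive
#' use: a yellow (high, 32-fold above median at +5) to blue (low) heatmap
#' with non-expressers in grey and cluster boundaries marked.
#'
#' @param x A `NormalizedMatrix`.
#' @param order A `DendrogramOrder` from [order_hierarchically()].
#' @param model The `ClusterModel`.
#' @param file Output PNG path.
#' @return The file path, invisibly.
#' @export
render_clustergram <- function(x, order, model, file) {
  stopifnot(inherits(x, "NormalizedMatrix"),
            inherits(order, "DendrogramOrder"),
            inherits(model, "ClusterModel"))
  clusters <- data.frame(cluster = model$assignments,
                         order = base::order(order$cell_order))
  v <- x$values[, order$gene_order, drop = FALSE]
  e <- x$expresser[, order$gene_order, drop = FALSE]
  .render_clustergram_tables(v, e, clusters, x$clip_bound, file)
  invisible(file)
}
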