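#' Assemble a run configuration
#'
#' Collects paths, hyperparameters, chain schedule, seed, and summary
#' cutoffs for [run_pipeline()]. Defaults mirror the model defaults
#' (K = 25, alpha = epsilon = 0.1) and the standard summary cutoffs
#' (0.02 for site classification, 0.05 for edge drawing, 1% minimum group
#' share, 95% credible level).
#'
#' @param counts path to the first-window count matrix.
#' @param out_dir output directory (created if missing).
#' @param counts_t2 optional path to a second-window count matrix; when
#'   given, the pipeline refits profiles with memberships frozen and reports
#'   temporal changes.
#' @param K,alpha,epsilon hyperparameters (see [ibc_hyper()]).
#' @param n_iter,burnin,thin chain schedule (see [run_gibbs()]).
#' @param seed integer seed recorded in every artifact.
#' @param site_cutoff,edge_cutoff,min_share,level summary settings.
#' @param graphml also write the union connectivity graph as GraphML
#'   (requires the igraph package).
#' @return list of class `ibc_config`.
#' @export
ibc_config <- function(counts, out_dir, counts_t2 = NULL,
                       K = 25L, alpha = 0.1, epsilon = 0.1,
                       n_iter = 10000L, burnin = 5000L, thin = 10L,
                       seed = 1L, site_cutoff = 0.02, edge_cutoff = 0.05,
                       min_share = 0.01, level = 0.95, graphml = FALSE) {
  cfg <- list(counts = counts, out_dir = out_dir, counts_t2 = counts_t2,
              K = as.integer(K), alpha = alpha, epsilon = epsilon,
              n_iter = as.integer(n_iter), burnin = as.integer(burnin),
              thin = as.integer(thin), seed = as.integer(seed),
              site_cutoff = site_cutoff, edge_cutoff = edge_cutoff,
              min_share = min_share, level = level, graphml = isTRUE(graphml))
  ibc_hyper(cfg$K, cfg$alpha, cfg$epsilon)        # validate
  .check_schedule(cfg$n_iter, cfg$burnin, cfg$thin)
  structure(cfg, class = "ibc_config")
}

#' Read a run configuration from JSON or YAML
#'
#' A flat document whose keys mirror the [ibc_config()] arguments; missing
#' keys fall back to the defaults, and `overrides` (e.g. from CLI flags)
#' take precedence over file values.
#'
#' @param path configuration file (`.json`, `.yaml`, or `.yml`).
#' @param overrides named list of values overriding the file.
#' @return an `ibc_config`.
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(ibc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(ibc_config, vals)
}

#' Run the full analysis pipeline
#'
#' Sequences the standard workflow on a count matrix: fit the mixture,
#' relabel the draws, and write summary tables (effective groups, site
#' classification, per-group edge lists); when a second-window count file is
#' configured, additionally refit the profiles with memberships frozen and
#' write the temporal change table. Every output is listed, with an MD5
#' checksum, in `manifest.json`; runs are reproducible bit-for-bit from
#' (inputs, config, seed).
#'
#' @param config an `ibc_config` (or a path accepted by [read_config()]).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (list with `outputs`, `checksums`,
#'   `config`, `version`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "ibc_config"))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out_dir, mode = 2L) != 0L) {
    stop(sprintf("output directory not writable: %s", config$out_dir), call. = FALSE)
  }
  outputs <- character(0)
  hyper <- ibc_hyper(config$K, config$alpha, config$epsilon)

  say("read", "reading counts from %s", config$counts)
  counts <- read_counts(config$counts)
  say("read", "%d individuals x %d locations, %d observations (seed %d)",
      nrow(counts), ncol(counts), sum(counts), config$seed)

  say("fit", "running %d sweeps (burnin %d, thin %d)",
      config$n_iter, config$burnin, config$thin)
  fit <- run_gibbs(counts, hyper, config$n_iter, config$burnin, config$thin,
                   seed = config$seed)
  fit <- relabel_samples(fit)

  groups <- effective_groups(fit, config$min_share)
  say("summarize", "%d effective group(s) covering %.1f%% of individuals",
      nrow(groups), 100 * attr(groups, "coverage"))
  f <- file.path(config$out_dir, "groups.csv")
  utils::write.csv(cbind(groups, coverage = attr(groups, "coverage")),
                   f, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, f)

  pm <- psi_mean(fit)
  sites <- mixed_membership_sites(pm, groups$group, config$site_cutoff)
  sites_flat <- sites
  sites_flat$groups <- vapply(sites$groups, paste, character(1L), collapse = ";")
  f <- file.path(config$out_dir, "sites.csv")
  utils::write.csv(sites_flat, f, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, f)

  edges <- do.call(rbind, lapply(groups$group, function(k) {
    group_edges(pm, k, config$edge_cutoff)
  }))
  f <- file.path(config$out_dir, "edges.csv")
  utils::write.csv(edges, f, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, f)

  if (config$graphml) {
    f <- file.path(config$out_dir, "edges.graphml")
    write_union_graphml(edges, f)
    outputs <- c(outputs, f)
  }

  f <- file.path(config$out_dir, "fit")
  outputs <- c(outputs, write_samples(fit, f))

  delta_skipped <- TRUE
  if (!is.null(config$counts_t2)) {
    say("refit", "conditional refit on %s with memberships frozen", config$counts_t2)
    counts2 <- read_counts(config$counts_t2)
    refit <- conditional_refit(counts2, posterior_modes(fit), hyper,
                               config$n_iter, config$burnin, config$thin,
                               seed = config$seed + 1L)
    delta <- delta_visitation(fit, refit, level = config$level,
                              groups = groups$group)
    f <- file.path(config$out_dir, "delta.csv")
    utils::write.csv(delta, f, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, f)
    outputs <- c(outputs, write_samples(refit, file.path(config$out_dir, "refit")))
    delta_skipped <- FALSE
  } else {
    say("refit", "no second-window counts configured; temporal comparison skipped")
  }

  manifest <- list(
    outputs = basename(outputs),
    checksums = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                        basename(outputs))),
    delta_skipped = delta_skipped,
    config = unclass(config),
    version = as.character(utils::packageVersion("ibclust"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  say("done", "wrote %d output file(s) to %s", length(outputs) + 1L, config$out_dir)
  invisible(manifest)
}

#' Write the union connectivity graph as GraphML
#'
#' Combines per-group edge lists (as produced by [group_edges()]) into one
#' undirected graph, with a `group` edge attribute, using the igraph package.
#'
#' @param edges data.frame with columns `from`, `to`, `group`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_union_graphml <- function(edges, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to", "group")],
                                     directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
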