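#' Run the full intron co-phylogeny pipeline
#'
#' Orchestrates the analysis end-to-end: obtain the two partitions
#' (either simulated with [simulate_cophylo_dataset()] or loaded from
#' alignment files), optionally scan query sequences for introns against
#' a reference CDS, estimate the ML tree of each partition, and run the
#' three co-speciation tests (reciprocal AU tests, the Huelsenbeck-Bull
#' LRT, and ParaFit).  All stage outputs and a JSON manifest land in
#' `config$out_dir`; rerunning with the same config reproduces the same
#' manifest body (no timestamps are written).
#'
#' The config is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{seed}{integer, mandatory: master seed for every stochastic
#'     stage.}
#'   \item{out_dir}{output directory, created if needed.}
#'   \item{simulate}{optional list of [simulate_cophylo_dataset()]
#'     arguments; if absent, `aln_host`/`aln_parasite` paths (FASTA or
#'     NEXUS by extension) must be given.}
#'   \item{scan}{optional list with `queries` and `reference` FASTA paths
#'     (and optionally `code`, `min_len`, `min_aa`).}
#'   \item{model}{model spec, e.g. `list(family = "GTR", alpha = 0.5,
#'     p_inv = 0.2)`; default GTR+G+I.}
#'   \item{replicates}{LRT bootstrap replicates (default 100).}
#'   \item{n_perm}{ParaFit permutations (default 999).}
#'   \item{n_rell}{AU RELL replicates per scale (default 2000).}
#'   \item{stages}{character subset of `c("scan", "trees", "au", "lrt",
#'     "parafit")` to run (default all applicable).}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return Object of class `run_report` (also serialised to
#'   `manifest.json`): intron table, tree files, AU, LRT and ParaFit
#'   results, and provenance (config hash, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed))
    stop("config validation: 'seed' is mandatory (set every stochastic ",
         "stage's seed before any compute)")
  if (is.null(config$out_dir)) stop("config validation: 'out_dir' missing")
  if (is.null(config$simulate) &&
      (is.null(config$aln_host) || is.null(config$aln_parasite)))
    stop("config validation: provide either 'simulate' or both ",
         "'aln_host' and 'aln_parasite'")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("scan", "trees", "au", "lrt", "parafit")
  seeds <- derive_seeds(config$seed, 6)
  model <- do.call(subst_model, config$model %||%
                     list(family = "GTR", alpha = 0.5, p_inv = 0.2))
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("cophylointron")),
    config_hash = unname(.config_hash(config)), seed = config$seed))
  out <- function(...) file.path(config$out_dir, ...)

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report[[name]] <<- res
    .write_state(out("state.json"), names(report))
    res
  }

  # --- data -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    ds <- run_stage("dataset", {
      d <- do.call(simulate_cophylo_dataset,
                   c(config$simulate, list(seed = seeds[[1]])))
      write_newick(d$host_tree, out("host_tree_true.nwk"))
      write_newick(d$parasite_tree, out("parasite_tree_true.nwk"))
      write_fasta(alignment_strings(d$aln_host), out("aln_host.fasta"))
      write_fasta(alignment_strings(d$aln_parasite),
                  out("aln_parasite.fasta"))
      write_links(d$links, out("links.tsv"))
      d
    })
    aln_h <- ds$aln_host; aln_p <- ds$aln_parasite; links <- ds$links
  } else {
    read_aln <- function(path) {
      if (grepl("\\.(nex|nexus)$", path, ignore.case = TRUE))
        read_nexus_alignment(path)
      else as_alignment(read_fasta(path))
    }
    aln_h <- read_aln(config$aln_host)
    aln_p <- read_aln(config$aln_parasite)
    links <- if (!is.null(config$links)) read_links(config$links)
             else data.frame(host = rownames(aln_h),
                             parasite = rownames(aln_p))
  }

  # --- scan -------------------------------------------------------------
  if ("scan" %in% stages && !is.null(config$scan)) {
    run_stage("scan", {
      sc <- config$scan
      res <- scan_introns(read_fasta(sc$queries),
                          read_fasta(sc$reference),
                          table = sc$code %||% 4L,
                          min_len = sc$min_len %||% 30L,
                          min_aa = sc$min_aa %||% 50L)
      utils::write.table(res$table, out("introns.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (length(res$introns))
        write_fasta(res$introns, out("introns.fasta"))
      res$table
    })
  }

  # --- trees ------------------------------------------------------------
  trees <- NULL
  if (any(c("trees", "au", "lrt", "parafit") %in% stages)) {
    trees <- run_stage("trees", {
      fh <- ml_search(aln_h, model, seed = seeds[[2]])
      fp <- ml_search(aln_p, model, seed = seeds[[3]])
      write_newick(fh$tree, out("tree_host_ml.nwk"))
      write_newick(fp$tree, out("tree_parasite_ml.nwk"))
      list(host = fh, parasite = fp,
           loglik = c(host = fh$loglik, parasite = fp$loglik))
    })
  }

  # --- reciprocal AU ----------------------------------------------------
  if ("au" %in% stages) {
    run_stage("au", {
      topo <- list(host_ml = trees$host$tree, parasite_ml = trees$parasite$tree)
      res <- list(
        on_host = au_test(topo, aln_h, model, seed = seeds[[4]],
                          n_rell = config$n_rell %||% 2000),
        on_parasite = au_test(topo, aln_p, model, seed = seeds[[4]] + 1,
                              n_rell = config$n_rell %||% 2000))
      list(host_rejects_parasite_topology = res$on_host$table$au_p[2],
           parasite_rejects_host_topology = res$on_parasite$table$au_p[1],
           detail = res)
    })
  }

  # --- Huelsenbeck-Bull LRT --------------------------------------------
  if ("lrt" %in% stages) {
    run_stage("lrt", {
      r <- hb_lrt(aln_h, aln_p, model, replicates =
                    config$replicates %||% 100, seed = seeds[[5]])
      utils::write.table(data.frame(null_d = r$null_d), out("null_d.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      r
    })
  }

  # --- ParaFit ----------------------------------------------------------
  if ("parafit" %in% stages) {
    run_stage("parafit", {
      parafit_test(patristic(trees$host$tree),
                   patristic(trees$parasite$tree), links,
                   n_perm = config$n_perm %||% 999, seed = seeds[[6]])
    })
  }

  report <- .serialise_report(report)
  jsonlite::write_json(report, out("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  structure(report, class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  # hash of the analytic configuration: the output location does not
  # change the computation, so it is excluded
  config <- config[setdiff(names(config), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config[order(names(config))], f, auto_unbox = TRUE,
                       digits = 10, force = TRUE)
  tools::md5sum(f)
}

.write_state <- function(path, done) {
  jsonlite::write_json(list(completed_stages = done), path,
                       auto_unbox = FALSE)
}

# Strip heavyweight objects down to the numbers a manifest should carry.
.serialise_report <- function(report) {
  slim <- report
  if (!is.null(slim$dataset))
    slim$dataset <- list(
      n_hosts = length(slim$dataset$host_tree$tip.label),
      n_bearing = length(slim$dataset$parasite_tree$tip.label),
      n_switches = sum(slim$dataset$events$type == "host_switch"),
      n_losses = sum(slim$dataset$events$type == "loss"))
  if (!is.null(slim$trees)) slim$trees <- as.list(slim$trees$loglik)
  if (!is.null(slim$au)) slim$au <- slim$au[c(
    "host_rejects_parasite_topology", "parasite_rejects_host_topology")]
  if (!is.null(slim$lrt))
    slim$lrt <- slim$lrt[c("loglik0", "loglik1", "d", "p", "replicates")]
  if (!is.null(slim$parafit))
    slim$parafit <- list(global_stat = slim$parafit$global_stat,
                         global_p = slim$parafit$global_p,
                         links = slim$parafit$links)
  slim
}
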