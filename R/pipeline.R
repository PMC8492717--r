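## ---- pipeline orchestration ------------------------------------------------

.cfg_error <- function(msg) stop(structure(
  class = c("mt_config_error", "error", "condition"),
  list(message = msg, call = NULL)))
.data_error <- function(msg) stop(structure(
  class = c("mt_data_error", "error", "condition"),
  list(message = msg, call = NULL)))

#' Validate a pipeline run configuration
#'
#' The configuration is a JSON file (or an equivalent list) with
#' blocks: `input` (`fasta`, `metadata`) or `synthetic` (generator
#' settings), optional `window` (`start`, `end`; 0-based half-open),
#' `missing_policy`, `pop_level`, `stages` (subset of `diversity`,
#' `amova`, `fst`, `mds`, `lineage`, `network`, `abc`), stage settings
#' (`bootstrap_B`, `n_perm`, `mj_epsilon`, `abc` block with
#' `scenarios_file`/`preset`, `priors_file`, `n_per_scenario`,
#' `tolerance`, `samples`, `L`), `seeds` (named, one per stochastic
#' stage), and `outdir`.
#'
#' @param cfg list or path to a JSON config.
#' @return Normalized config list.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) .cfg_error(paste("config file not found:", cfg))
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  }
  if (is.null(cfg$outdir)) .cfg_error("config needs `outdir`")
  if (is.null(cfg$stages)) cfg$stages <-
      c("diversity", "amova", "fst", "mds", "network")
  known <- c("diversity", "amova", "fst", "mds", "lineage", "network", "abc")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) .cfg_error(paste("unknown stage(s):",
                                    paste(bad, collapse = ", ")))
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    .cfg_error("config needs an `input` or `synthetic` block")
  if (!is.null(cfg$input)) {
    for (f in c("fasta", "metadata"))
      if (is.null(cfg$input[[f]]) || !file.exists(cfg$input[[f]]))
        .cfg_error(paste("input", f, "missing or not found"))
  }
  if (is.null(cfg$missing_policy)) cfg$missing_policy <- "exclude_site"
  if (is.null(cfg$pop_level)) cfg$pop_level <- "breed"
  if (is.null(cfg$bootstrap_B)) cfg$bootstrap_B <- 2000L
  if (is.null(cfg$n_perm)) cfg$n_perm <- 1000L
  if (is.null(cfg$mj_epsilon)) cfg$mj_epsilon <- 0L
  if (is.null(cfg$seeds)) cfg$seeds <- list()
  need_seeds <- intersect(c("amova", "fst", "abc"), cfg$stages)
  for (s in need_seeds)
    if (is.null(cfg$seeds[[s]]))
      .cfg_error(paste0("stage '", s, "' is stochastic: config must name ",
                        "seeds$", s))
  if ("abc" %in% cfg$stages) {
    ab <- cfg$abc
    if (is.null(ab)) .cfg_error("abc stage enabled but no `abc` block")
    if (is.null(ab$preset) && is.null(ab$scenarios_file))
      .cfg_error("abc block needs `preset` or `scenarios_file`")
    if (!is.null(ab$scenarios_file) && !file.exists(ab$scenarios_file))
      .cfg_error("abc scenarios_file not found")
    if (!is.null(ab$priors_file) && !file.exists(ab$priors_file))
      .cfg_error("abc priors_file not found")
    if (is.null(ab$n_per_scenario)) ab$n_per_scenario <- 20000L
    if (is.null(ab$tolerance)) ab$tolerance <- 0.01
    if (is.null(ab$L)) ab$L <- 600L
    if (is.null(ab$samples)) .cfg_error("abc block needs `samples`")
    cfg$abc <- ab
  }
  cfg
}

.md5 <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the full phylogeography workflow from one configuration
#'
#' Executes the requested stages in order (diversity, AMOVA, pairwise
#' Phi_ST, MDS, lineage assignment, haplotype network, ABC model
#' choice + parameter estimation), writes every export under
#' `cfg$outdir`, and emits a JSON manifest recording input hashes,
#' seeds, package version and per-stage outputs.  A stage failure
#' leaves earlier outputs in place and records the failing stage in the
#' manifest (`status = "failed"`).
#'
#' @param cfg configuration list or JSON path (see [validate_config()]).
#' @return The manifest, invisibly; its `status` element is `"ok"` or
#'   `"failed"`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mtphylogeo",
                   version = as.character(utils::packageVersion("mtphylogeo")),
                   seeds = cfg$seeds, stages = list(), status = "ok")
  if (!is.null(cfg$input)) {
    a <- tryCatch(read_alignment(cfg$input$fasta, cfg$input$metadata),
                  error = function(e) .data_error(conditionMessage(e)))
    manifest$inputs <- .md5(c(cfg$input$fasta, cfg$input$metadata))
  } else {
    gen_args <- cfg$synthetic
    gc_ <- do.call(generator_config, if (is.list(gen_args)) gen_args else list())
    gen <- generate_breeds(gc_)
    a <- gen$alignment
    fasta <- file.path(cfg$outdir, "synthetic.fasta")
    meta <- file.path(cfg$outdir, "synthetic.tsv")
    write_alignment(a, fasta, meta)
    jsonlite::write_json(list(lineage = as.list(gen$truth$lineage),
                              overlap_flag = gen$truth$overlap_flag),
                         file.path(cfg$outdir, "truth.json"),
                         auto_unbox = TRUE)
    manifest$inputs <- .md5(c(fasta, meta))
  }
  if (!is.null(cfg$window))
    a <- extract_window(a, cfg$window$start, cfg$window$end)
  outfile <- function(name) file.path(cfg$outdir, name)
  stage <- function(name, fun) {
    if (!(name %in% cfg$stages) || manifest$status != "ok")
      return(invisible(NULL))
    res <- tryCatch({
      files <- fun()
      manifest$stages[[name]] <<- list(status = "ok",
                                       outputs = .md5(files))
    }, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
    })
    invisible(res)
  }
  fst_cache <- NULL
  stage("diversity", function() {
    f <- outfile("diversity.tsv")
    utils::write.table(diversity_table(a, cfg$missing_policy, cfg$pop_level),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })
  stage("amova", function() {
    res <- amova(a, pop_level = cfg$pop_level, n_perm = cfg$n_perm,
                 missing_policy = cfg$missing_policy,
                 seed = cfg$seeds$amova)
    f <- outfile("amova.tsv")
    utils::write.table(res$components, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  })
  stage("fst", function() {
    fst_cache <<- pairwise_fst(a, pop_level = cfg$pop_level,
                               n_perm = cfg$n_perm,
                               missing_policy = cfg$missing_policy,
                               seed = cfg$seeds$fst %||% cfg$seeds$amova)
    f <- outfile("fst.tsv")
    write_fst_matrix(fst_cache, f)
    f
  })
  stage("mds", function() {
    if (is.null(fst_cache))
      fst_cache <<- pairwise_fst(a, pop_level = cfg$pop_level,
                                 missing_policy = cfg$missing_policy)
    f <- outfile("mds.tsv")
    write_mds(mds_from_fst(fst_cache), f)
    f
  })
  stage("lineage", function() {
    refs <- if (!is.null(cfg$refs_fasta))
      read_alignment(cfg$refs_fasta, cfg$refs_metadata)
    else generate_reference_fixture(L = a$L)
    la <- assign_lineage(a, refs)
    f <- outfile("lineage.tsv")
    utils::write.table(
      data.frame(sample_id = names(la$assignment),
                 lineage = unname(la$assignment)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })
  stage("network", function() {
    h <- collapse_haplotypes(a, cfg$missing_policy, cfg$pop_level)
    net <- median_joining(h, epsilon = cfg$mj_epsilon)
    f1 <- outfile("network_edges.tsv"); f2 <- outfile("network_nodes.tsv")
    write_network(net, f1, f2)
    c(f1, f2)
  })
  stage("abc", function() {
    ab <- cfg$abc
    scns <- if (!is.null(ab$scenarios_file)) parse_scenarios(ab$scenarios_file)
            else default_scenarios(ab$preset)
    pri <- if (!is.null(ab$priors_file)) parse_priors(ab$priors_file)
           else prior_spec()
    samples <- unlist(ab$samples)
    rt <- build_reference_table(scns, pri, ab$n_per_scenario, samples,
                                ab$L, seed = cfg$seeds$abc)
    obs <- summary_stats(a, pops = scns[[1]]$pops,
                         pop_level = "metapopulation")
    mc <- model_choice(rt, obs, ab$tolerance)
    f1 <- outfile("abc_model_choice.json")
    write_model_choice(mc, f1)
    post <- estimate_parameters(rt, mc$winner, obs, ab$tolerance)
    f2 <- outfile("abc_posterior.tsv")
    utils::write.table(post$summary, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(f1, f2)
  })
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `run <config.json>` (full pipeline),
#' `simulate-data <outdir> [seed]`, and single-stage shortcuts
#' `diversity|amova|fst|mds|network <fasta> <metadata> <outdir>`.
#' Exit codes: 0 success, 2 config error, 3 data error, 4 numerical
#' failure.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the actual command line).
#' @return Integer exit code, invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(args)) .cfg_error("usage: mtphylogeo <subcommand> ...")
    sub <- args[1]
    if (sub == "run") {
      if (length(args) < 2L) .cfg_error("run: need a config path")
      man <- run_pipeline(args[2])
      if (man$status != "ok") {
        message("stage failed: ", man$failed_stage)
        return(invisible(4L))
      }
      0L
    } else if (sub == "simulate-data") {
      if (length(args) < 2L) .cfg_error("simulate-data: need an outdir")
      seed <- if (length(args) >= 3L) as.integer(args[3]) else 1L
      dir.create(args[2], recursive = TRUE, showWarnings = FALSE)
      gen <- generate_breeds(generator_config(seed = seed))
      write_alignment(gen$alignment, file.path(args[2], "synthetic.fasta"),
                      file.path(args[2], "synthetic.tsv"))
      0L
    } else if (sub %in% c("diversity", "amova", "fst", "mds", "network")) {
      if (length(args) < 4L) .cfg_error(paste(sub, ": need <fasta> <metadata> <outdir>"))
      cfg <- list(input = list(fasta = args[2], metadata = args[3]),
                  outdir = args[4], stages = sub,
                  n_perm = 0L, seeds = list(amova = 1L, fst = 1L))
      man <- run_pipeline(cfg)
      if (man$status != "ok") return(invisible(4L))
      0L
    } else .cfg_error(paste("unknown subcommand:", sub))
  },
  mt_config_error = function(e) { message("config error: ", e$message); 2L },
  mt_data_error = function(e) { message("data error: ", e$message); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 4L })
  invisible(code)
}
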