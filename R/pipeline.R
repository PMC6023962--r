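# End-to-end orchestration: simulate -> split IF/OF -> fit generation model
# on OF -> fit selection model on IF -> clones -> statistics, with a JSON
# manifest recording configuration, seeds and output digests.

#' Run the full analysis workflow
#'
#' Executes the stages of the repertoire analysis in dependency order on a
#' simulated repertoire: simulate out-of-frame and productive pools, fit the
#' generation model to the out-of-frame reads, sample the pre-selection
#' ensemble, fit the selection model to the productive reads, detect clones,
#' and compute the IF/OF contrast statistics. All artifacts are written to
#' `config$out_dir` together with a manifest of digests; rerunning with the
#' same config and seed reproduces the digests.
#'
#' @param config A list (or path to a YAML file) with fields `germline`
#'   (path; default the packaged toy set), `seed` (required), `n_of`, `n_if`
#'   (pool sizes), `out_dir` (required), and optional `d_max`, `i_max`,
#'   `L_max`, `min_count`, `tol_gen`, `tol_sel`, `max_iter_gen`,
#'   `max_iter_sel`, `pre_factor` (pre-sample size as a multiple of `n_if`),
#'   `cutoff`, `selection` (named amino-acid factor list applied to the IF
#'   pool).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (req in c("seed", "out_dir")) {
    if (is.null(config[[req]])) stopf("config is missing required field '%s'", req)
  }
  germline_path <- config$germline %||%
    system.file("extdata", "toy_germline.fasta", package = "igkselect")
  if (!file.exists(germline_path))
    stopf("pre-flight: germline file not found: %s", germline_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  seed <- as.integer(config$seed)
  n_of <- config$n_of %||% 5000L
  n_if <- config$n_if %||% 5000L
  d_max <- config$d_max %||% 8L
  i_max <- config$i_max %||% 10L
  pre_factor <- config$pre_factor %||% 5

  manifest <- list(config = config, started = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(utils::packageVersion("igkselect")),
                   stages = list())
  digest <- function(path) unname(tools::md5sum(path))
  outfile <- function(name) file.path(config$out_dir, name)
  record <- function(stage, files, pars) {
    manifest$stages[[stage]] <<- list(
      files = lapply(stats::setNames(files, basename(files)), digest),
      parameters = pars)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$partial <<- TRUE
      jsonlite::write_json(manifest, outfile("manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  germline <- run_stage("germline", load_germline(germline_path))
  record("germline", germline_path, list(path = germline_path))

  params <- toy_generation_params(germline, i_max = i_max)
  sel_fun <- NULL
  if (!is.null(config$selection))
    sel_fun <- aa_factor_selection(unlist(config$selection))

  pools <- run_stage("simulate", {
    of_pool <- simulate_pool(n_of, params, germline, frame = "out_of_frame",
                             seed = derive_seed(seed, "of"))
    if_pool <- simulate_pool(n_if, params, germline, frame = "productive",
                             selection = sel_fun,
                             seed = derive_seed(seed, "if"))
    write_repertoire(of_pool, outfile("of_pool.fasta"))
    write_truth(of_pool, outfile("of_pool.truth.tsv"))
    write_repertoire(if_pool, outfile("if_pool.fasta"))
    write_truth(if_pool, outfile("if_pool.truth.tsv"))
    list(of = of_pool, `if` = if_pool)
  })
  of_pool <- pools$of
  if_pool <- pools$`if`
  record("simulate", outfile(c("of_pool.fasta", "of_pool.truth.tsv",
                               "if_pool.fasta", "if_pool.truth.tsv")),
         list(n_of = n_of, n_if = n_if, seed_of = derive_seed(seed, "of"),
              seed_if = derive_seed(seed, "if"),
              selection = config$selection))

  gen_fit <- run_stage("fit-gen",
    fit_generation_model(of_pool, germline, d_max = d_max, i_max = i_max,
                         tol = config$tol_gen %||% 1e-4,
                         max_iter = config$max_iter_gen %||% 60))
  write_generation_model(gen_fit, outfile("generation_model.json"))
  record("fit-gen", outfile("generation_model.json"),
         list(d_max = d_max, i_max = i_max, n_used = gen_fit$n_used,
              n_excluded = gen_fit$n_excluded, n_iter = gen_fit$n_iter,
              logLik = unclass(logLik(gen_fit))))

  n_pre <- max(ceiling(pre_factor * n_if), config$n_pre_min %||% 20000L)
  pre <- run_stage("sample-pre",
    sample_pre_repertoire(gen_fit, n = n_pre, seed = derive_seed(seed, "pre")))

  sel_fit <- run_stage("fit-sel",
    fit_selection_model(if_pool, pre, L_max = config$L_max %||% 19,
                        tol = config$tol_sel %||% 1e-4,
                        max_iter = config$max_iter_sel %||% 100,
                        min_count = config$min_count %||% 50))
  write_selection_model(sel_fit, outfile("selection_model.json"))
  write_heatmap_tsv(sel_fit, outfile("selection_heatmap.tsv"))
  record("fit-sel", outfile(c("selection_model.json", "selection_heatmap.tsv")),
         list(n_pre = n_pre, seed_pre = derive_seed(seed, "pre"),
              min_count = config$min_count %||% 50,
              n_iter = sel_fit$diagnostics$n_iter))

  clones <- run_stage("clones",
    detect_clones(if_pool, germline, cutoff = config$cutoff %||% 4))
  utils::write.table(clones, outfile("clones.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("clones", outfile("clones.tsv"),
         list(cutoff = config$cutoff %||% 4, n_clones = length(unique(clones$clone_id))))

  stats <- run_stage("stats", {
    anc <- clones$read_id[clones$is_ancestor]
    asg_if <- assign_vj(if_pool, germline)
    if_cdr3 <- extract_cdr3(if_pool, asg_if, germline)
    if_cdr3 <- if_cdr3[if_cdr3$read_id %in% anc, , drop = FALSE]
    of_clones <- detect_clones(of_pool, germline, cutoff = config$cutoff %||% 4)
    asg_of <- assign_vj(of_pool, germline)
    of_cdr3 <- extract_cdr3(of_pool, asg_of, germline)
    of_cdr3 <- of_cdr3[of_cdr3$read_id %in%
                         of_clones$read_id[of_clones$is_ancestor], , drop = FALSE]
    stats_report(if_cdr3, of_cdr3)
  })
  jsonlite::write_json(unclass(stats), outfile("stats_report.json"),
                       auto_unbox = TRUE, digits = NA)
  record("stats", outfile("stats_report.json"),
         list(sd_rel_diff_length = stats$sd_rel_diff_length))

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
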