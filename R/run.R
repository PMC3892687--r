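#' Look up a bundled case-study model by id
#'
#' Ids are `pk_<variant>` and `gln_<variant>` (see [pk_model()] and
#' [gln_model()]); [list_bundles()] enumerates them.
#'
#' @param id bundle id, e.g. `"pk_linear_sde"` or `"gln_rmm"`.
#' @return a `case_bundle`.
#' @export
get_bundle <- function(id) {
  if (startsWith(id, "pk_")) return(pk_model(sub("^pk_", "", id)))
  if (startsWith(id, "gln_")) return(gln_model(sub("^gln_", "", id)))
  stop("unknown model id: ", id)
}

#' @rdname get_bundle
#' @export
list_bundles <- function() {
  c(paste0("pk_", c("truth", "mm", "mm_final", "linear", "linear_sde",
                    "extended", "extended_full", paste0("M", 1:8))),
    paste0("gln_", c("mm", "rmm", "e1rmm", "e2rmm", "mm_ext_W")))
}

#' Serialize / restore a viable sample
#'
#' Columnar CSV (one column per parameter in log10 units, plus `cost`,
#' `viable`, `weight`, `chain`) with a JSON sidecar holding the box, rule,
#' cutoff and seed.
#'
#' @param sample a `viable_sample`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return the path ([write_sample()]) / a `viable_sample` ([read_sample()]).
#' @export
write_sample <- function(sample, path) {
  df <- as.data.frame(sample$points)
  df$cost <- sample$costs
  df$viable <- sample$viable
  df$weight <- sample$weights
  df$chain <- sample$chain
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(box = list(params = colnames(sample$box),
                          lo = unname(sample$box[1, ]),
                          hi = unname(sample$box[2, ])),
               cutoff = sample$cutoff, seed = sample$seed,
               rule = if (!is.null(sample$rule)) unclass(sample$rule),
               vol_fraction = sample$vol_fraction,
               status = sample$status)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pnames <- side$box$params
  box <- rbind(lo = side$box$lo, hi = side$box$hi)
  colnames(box) <- pnames
  structure(list(points = as.matrix(df[pnames]), costs = df$cost,
                 viable = df$viable, weights = df$weight, chain = df$chain,
                 box = box, cutoff = as.numeric(side$cutoff),
                 seed = side$seed,
                 rule = side$rule, vol_fraction = side$vol_fraction,
                 status = side$status %||% "ok"),
            class = "viable_sample")
}

#' Run one workflow step from a configuration
#'
#' Thin orchestration layer tying the workflow together for scripted use:
#' each step reads its inputs from the config, calls the corresponding
#' package functions, writes versioned CSV/JSON outputs into `out_dir`, and
#' drops a manifest (`manifest.json`: config hash, seeds, package version)
#' so a saved config re-executes to identical outputs.  Unknown config keys
#' are rejected.
#'
#' Steps and their keys (besides `out_dir`, `seed`, `model`):
#' `generate` (`case`: `pk`|`gln`); `explore` (`data`, `delta_orders` or
#' `alpha`, `n_chains`, `n_steps`, `n_screen`); `diagnose` (`sample`,
#' `sigma_ids`, `epsilon_log10`); `infer_hidden` (`sample`, `data`,
#' `grid_from`, `grid_to`, `grid_by`, `state`); `compare` (`models`,
#' `data`, `n_draws`).
#'
#' A single global seed expands to per-stage seeds by a fixed offset scheme
#' (stage index * 1000 added to the seed) so stages re-run independently
#' yet reproducibly.
#'
#' @param step one of `"generate"`, `"explore"`, `"diagnose"`,
#'   `"infer_hidden"`, `"compare"`.
#' @param config named list, or path to a JSON config file.
#' @return (invisibly) a list of the artifact paths written.
#' @export
run_step <- function(step = c("generate", "explore", "diagnose",
                              "infer_hidden", "compare"),
                     config) {
  step <- match.arg(step)
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  allowed <- list(
    generate = c("case", "seed", "out_dir", "rho"),
    explore = c("model", "data", "seed", "out_dir", "delta_orders", "alpha",
                "n_chains", "n_steps", "n_screen"),
    diagnose = c("sample", "sigma_ids", "epsilon_log10", "out_dir"),
    infer_hidden = c("model", "sample", "data", "grid_from", "grid_to",
                     "grid_by", "state", "subsample", "seed", "out_dir"),
    compare = c("models", "data", "n_draws", "seed", "out_dir"))
  bad <- setdiff(names(config), allowed[[step]])
  if (length(bad))
    stop("invalid config key(s) for step '", step, "': ",
         paste(bad, collapse = ", "))
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- seed + 1000L * match(step, names(allowed))
  log_line <- function(...) message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                    sprintf(...))
  artifacts <- list()

  if (step == "generate") {
    dat <- switch(config$case,
                  pk = if (is.null(config$rho)) pk_generate(stage_seed)
                       else pk_generate(stage_seed, rho = config$rho),
                  gln = if (is.null(config$rho)) gln_generate(stage_seed)
                        else gln_generate(stage_seed, rho = config$rho),
                  stop("unknown case: ", config$case))
    p <- file.path(out_dir, paste0(config$case, "_data.csv"))
    write_dataset(dat, p)
    log_line("wrote %d data points to %s", nrow(dat), p)
    artifacts$data <- p
  } else if (step == "explore") {
    b <- get_bundle(config$model)
    dat <- read_dataset(config$data)
    costfn <- function(th) ekf_cost(b$model, th, dat)$value
    rule <- if (!is.null(config$alpha))
      ode_threshold(dat, config$alpha)
    else viability_rule("sde", delta_orders = config$delta_orders %||% 5)
    s <- explore_settings(
      corner_ids = grep("^sigma_", b$model$param_names, value = TRUE))
    for (k in c("n_chains", "n_steps", "n_screen"))
      if (!is.null(config[[k]])) s[[k]] <- as.integer(config[[k]])
    smp <- explore(costfn, b$box, s, seed = stage_seed, rule = rule)
    if (smp$status != "ok") log_line("status: %s", smp$status)
    p <- file.path(out_dir, paste0(config$model, "_sample.csv"))
    write_sample(smp, p)
    log_line("explore: %d/%d viable, cutoff %.4g -> %s",
             sum(smp$viable), length(smp$costs), smp$cutoff, p)
    artifacts$sample <- p
  } else if (step == "diagnose") {
    smp <- read_sample(config$sample)
    ids <- config$sigma_ids %||% grep("^sigma_", colnames(smp$points), value = TRUE)
    dg <- diagnose_diffusion(smp, ids, config$epsilon_log10 %||% 1.0)
    p <- file.path(out_dir, "diagnosis.json")
    jsonlite::write_json(list(per_sigma = dg$per_sigma, subsets = dg$subsets,
                              epsilon_log10 = dg$epsilon_log10,
                              n_viable = dg$n_viable),
                         p, auto_unbox = TRUE, digits = NA)
    log_line("diagnosis written to %s", p)
    artifacts$diagnosis <- p
  } else if (step == "infer_hidden") {
    b <- get_bundle(config$model)
    smp <- read_sample(config$sample)
    dat <- read_dataset(config$data)
    grid <- seq(config$grid_from, config$grid_to, by = config$grid_by)
    hid <- infer_hidden(b$model, smp, dat, grid, state = config$state,
                        subsample = config$subsample %||% 300L,
                        seed = stage_seed)
    p <- file.path(out_dir, "hidden_trajectory.csv")
    utils::write.csv(data.frame(time = hid$time, mean = hid$mean, se = hid$se),
                     p, row.names = FALSE)
    log_line("hidden '%s' trajectory (n = %d viable points) -> %s",
             hid$state, hid$n, p)
    artifacts$hidden <- p
  } else if (step == "compare") {
    ids <- config$models
    bundles <- lapply(ids, get_bundle)
    dat <- read_dataset(config$data)
    cmp <- posterior_probs(stats::setNames(lapply(bundles, `[[`, "model"), ids),
                           dat, lapply(bundles, `[[`, "box"),
                           n_draws = as.integer(config$n_draws %||% 1000L),
                           seed = stage_seed)
    p <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(list(table = cmp$table, log10_bf = cmp$log10_bf,
                              n_draws = cmp$n_draws, seed = cmp$seed),
                         p, auto_unbox = TRUE, digits = NA)
    log_line("comparison written to %s", p)
    artifacts$comparison <- p
  }

  # the hashed config excludes the output location, so the same analysis
  # written to two directories yields identical manifests
  cfg <- config[setdiff(names(config), "out_dir")]
  cfg_path <- file.path(out_dir, paste0(step, "_config.json"))
  jsonlite::write_json(cfg[order(names(cfg))], cfg_path,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(step = step,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = seed, stage_seed = stage_seed,
                   package_version = as.character(utils::packageVersion("topaug")),
                   artifacts = lapply(artifacts, basename))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}
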