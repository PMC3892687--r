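#' Time-series measurement datasets
#'
#' A `ta_dataset` is a long-format table with columns `time`, `observable`,
#' `value` and `sd` (per-point measurement standard deviation), plus
#' metadata on the noise model used to generate or annotate it.  Different
#' observables may be sampled on different schedules.
#'
#' @param df data.frame with columns `time`, `observable`, `value` and
#'   optionally `sd`.
#' @param noise noise-model metadata: `list(type = "fixed")` or
#'   `list(type = "proportional", rho =, sd_floor =)`.  When `sd` is absent
#'   from `df` it is filled in from the proportional model applied to the
#'   measured values, floored at `y_floor`.
#' @param y_floor floor for \eqn{|y|} when deriving proportional noise SDs
#'   from measured values (keeps the cost well-defined near zero
#'   concentrations).
#' @return object of class `ta_dataset` (a data.frame).
#' @export
ta_dataset <- function(df, noise = list(type = "fixed"), y_floor = 1e-6) {
  need <- c("time", "observable", "value")
  if (!all(need %in% names(df))) stop("dataset needs columns time, observable, value")
  df <- df[order(df$time, df$observable), , drop = FALSE]
  df$observable <- as.character(df$observable)
  if (is.null(df$sd)) {
    if (!identical(noise$type, "proportional") || is.null(noise$rho))
      stop("`sd` column absent: supply a proportional noise model with `rho`")
    df$sd <- noise$rho * pmax(abs(df$value), y_floor)
  }
  if (any(!is.finite(df$value)) || any(!is.finite(df$sd)))
    stop("dataset values and sds must be finite")
  if (nrow(df) > 0 && any(df$sd <= 0))
    stop("noise standard deviations must be strictly positive")
  structure(df[c("time", "observable", "value", "sd")],
            class = c("ta_dataset", "data.frame"),
            noise = noise)
}

#' @export
print.ta_dataset <- function(x, ...) {
  obs <- table(x$observable)
  cat(sprintf("<ta_dataset> %d points (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(obs), obs), collapse = ", ")))
  NextMethod()
}

#' Read / write a dataset as CSV
#'
#' Canonical on-disk form: columns `time, observable, value, sd` (the `sd`
#' column may be omitted when a proportional noise coefficient is supplied).
#'
#' @param path file path.
#' @param rho optional proportional noise coefficient used to reconstruct
#'   `sd` from measured values when the file has no `sd` column.
#' @param y_floor see [ta_dataset()].
#' @return a `ta_dataset` ([read_dataset()]) or the path, invisibly
#'   ([write_dataset()]).
#' @export
read_dataset <- function(path, rho = NULL, y_floor = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  noise <- if (is.null(df$sd)) list(type = "proportional", rho = rho, sd_floor = 0)
           else list(type = "fixed")
  ta_dataset(df, noise = noise, y_floor = y_floor)
}

#' @rdname read_dataset
#' @param data a `ta_dataset`.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

# wide view aligned with a model's observables: times vector plus K x p
# value and sd matrices with NA marking unobserved combinations
dataset_wide <- function(data, obs_names) {
  unk <- setdiff(unique(data$observable), obs_names)
  if (length(unk))
    stop("dataset observables not covered by the model output map: ",
         paste(unk, collapse = ", "))
  times <- sort(unique(data$time))
  K <- length(times); p <- length(obs_names)
  Y <- matrix(NA_real_, K, p, dimnames = list(NULL, obs_names))
  SD <- Y
  ki <- match(data$time, times)
  ji <- match(data$observable, obs_names)
  Y[cbind(ki, ji)] <- data$value
  SD[cbind(ki, ji)] <- data$sd
  list(times = times, Y = Y, SD = SD)
}

#' Generate noisy observations from a simulated trajectory
#'
#' Applies the measurement model to a trajectory.  In proportional mode
#' \eqn{y_k = h(x(t_k)) (1 + \rho \epsilon_k)} with
#' \eqn{\epsilon_k \sim N(0,1)} i.i.d., and the stored noise SD for point
#' \eqn{k} is \eqn{\max(\rho |h(x(t_k))|, sd_{floor})} (evaluated from the
#' noiseless simulated output).  In fixed mode, additive Gaussian noise with
#' the given SD is used.
#'
#' @param traj a `ta_trajectory` from [simulate_ode()].
#' @param model the `dynmodel` providing the output map.
#' @param noise `list(type = "proportional", rho =, sd_floor = 0)` or
#'   `list(type = "fixed", sd =)`.
#' @param seed integer seed (reproducible).
#' @param schedule optional named list mapping observable names to the time
#'   points at which they are sampled (must be a subset of `traj$times`);
#'   default: all trajectory times for all observables.
#' @return a `ta_dataset`.
#' @export
generate_observations <- function(traj, model, noise, seed = 1L, schedule = NULL) {
  obs <- model$obs_states
  if (is.null(schedule))
    schedule <- stats::setNames(rep(list(traj$times), length(obs)), names(obs))
  type <- noise$type %||% "fixed"
  if (type == "proportional") {
    rho <- noise$rho
    if (is.null(rho) || rho < 0) stop("proportional mode needs rho >= 0")
    sd_floor <- noise$sd_floor %||% 0
  }
  set.seed(seed)
  rows <- lapply(names(obs), function(ob) {
    tt <- schedule[[ob]]
    idx <- match(tt, traj$times)
    if (anyNA(idx)) stop("schedule times for ", ob, " not on the trajectory grid")
    h <- traj$states[idx, obs[[ob]]]
    eps <- stats::rnorm(length(tt))
    if (type == "proportional") {
      y <- h * (1 + rho * eps)
      s <- pmax(rho * abs(h), sd_floor)
      if (rho == 0) y <- h
    } else {
      s <- rep_len(noise$sd, length(tt))
      y <- h + s * eps
    }
    data.frame(time = tt, observable = ob, value = y, sd = s)
  })
  df <- do.call(rbind, rows)
  if (any(df$sd <= 0)) {
    # noiseless generation (rho = 0 with no floor): keep points but give
    # them a unit placeholder SD so downstream code can still display them
    if ((noise$rho %||% 1) == 0 && (noise$sd_floor %||% 0) == 0)
      df$sd[df$sd <= 0] <- 1
  }
  ta_dataset(df, noise = noise)
}
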