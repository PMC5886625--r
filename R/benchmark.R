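## Benchmark sweeps: sample network -> (noise-free precision | OU
## surrogate) -> estimate -> evaluate, repeated over seeds derived from a
## master seed so runs are reproducible and order-independent.

apply_sweep <- function(cfg, param, value) {
  switch(param,
    spectral_radius = {
      cfg$network$spectral_radius <- value
      cfg$simulation$spectral_radius <- value
    },
    connection_prob = cfg$network$connection_prob <- value,
    n_nodes = cfg$network$n_nodes <- as.integer(value),
    background_prob = cfg$network$background_prob <- value,
    sigma_obs = cfg$noise$sigma_obs <- value,
    observed_fraction = cfg$noise$observed_fraction <- value,
    T = cfg$simulation$T <- value,
    tau = cfg$simulation$tau <- value,
    stop("unknown sweep parameter: ", param))
  cfg
}

control_from_config <- function(cfg) {
  do.call(unitary_control,
          cfg$optimizer[intersect(names(cfg$optimizer),
                                  names(formals(unitary_control)))])
}

#' One configured simulate-and-estimate run
#'
#' Samples a ground-truth network from the config, produces its noise-free
#' precision matrix or a long OU surrogate covariance, runs the estimator
#' and scores it against the (skeleton) ground truth.  Background
#' connections, observation noise and partial observation are applied when
#' the config requests them; evaluation always targets the skeleton.
#'
#' @param config a [zlconn_config()].
#' @param path `"noise_free"` (analytic precision) or `"ou"` (simulated
#'   surrogate covariance).
#' @param seed integer seed covering network sampling and simulation.
#' @return a list with `fit` (the `effconn` object), `G_true` (skeleton
#'   restricted to observed nodes), `nodes`, and `metrics`.
#' @export
run_single <- function(config = zlconn_config(),
                       path = c("noise_free", "ou"), seed = 1) {
  path <- match.arg(path)
  stopifnot(inherits(config, "zlconn_config"))
  set.seed(seed)
  net <- config$network
  sim <- config$simulation
  n <- net$n_nodes
  rho <- if (path == "ou") sim$spectral_radius else net$spectral_radius
  G <- sample_er_network(n, net$connection_prob, rho,
                         net$inhibitory_fraction)
  Gfull <- if (net$background_prob > 0)
    add_background(G, net$background_prob,
                   net$background_radius_fraction * rho) else G
  control <- control_from_config(config)
  idx <- seq_len(n)
  if (path == "noise_free") {
    fit <- effconn(noise_free_precision(Gfull), input = "precision",
                   control = control)
  } else {
    model <- ou_model(Gfull, tau = sim$tau, dt = sim$dt, T = sim$T)
    sc <- surrogate_covariance(model, hrf = sim$hrf,
                               sigma_obs = config$noise$sigma_obs,
                               noise = sim$noise_model)
    Cm <- sc$C
    if (config$noise$observed_fraction < 1) {
      k <- max(2L, round(config$noise$observed_fraction * n))
      idx <- sort(sample.int(n, k))
      Cm <- Cm[idx, idx]
    }
    fit <- effconn(Cm, input = "covariance", control = control)
  }
  G_true <- G[idx, idx]
  thr <- config$evaluation$threshold
  if (is.null(thr) || is.na(thr)) thr <- NULL
  list(fit = fit, G_true = G_true, nodes = idx,
       metrics = performance_report(coef(fit), G_true, threshold = thr))
}

#' Parameter sweep benchmark
#'
#' Repeats [run_single()] over a grid of values of one parameter, with
#' per-run seeds drawn deterministically from the master seed (so the
#' sweep is reproducible and repetitions are independent).
#'
#' @param config base [zlconn_config()].
#' @param sweep parameter name: one of `spectral_radius`,
#'   `connection_prob`, `n_nodes`, `background_prob`, `sigma_obs`,
#'   `observed_fraction`, `T`, `tau`.
#' @param values numeric vector of sweep values.
#' @param repetitions runs per value (default from the config).
#' @param path forwarded to [run_single()].
#' @return an object of class `zlconn_benchmark`: `results` (one row per
#'   run: value, repetition, seed, metrics, optimizer iterations) and
#'   `summary` (mean and sd of each metric per value).
#' @export
run_benchmark <- function(config = zlconn_config(), sweep, values,
                          repetitions = config$repetitions,
                          path = c("noise_free", "ou")) {
  path <- match.arg(path)
  stopifnot(length(values) >= 1, repetitions >= 1)
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(values) * repetitions),
                  nrow = length(values))
  rows <- vector("list", length(values) * repetitions)
  k <- 0
  for (i in seq_along(values)) {
    cfg_i <- apply_sweep(config, sweep, values[i])
    for (r in seq_len(repetitions)) {
      run <- run_single(cfg_i, path = path, seed = seeds[i, r])
      k <- k + 1
      rows[[k]] <- data.frame(value = values[i], repetition = r,
                              seed = seeds[i, r],
                              as.data.frame(run$metrics),
                              iterations = run$fit$iterations)
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- c("auc", "prs", "pcc", "fn_rate", "fp_rate",
                   "sign_accuracy")
  summ <- do.call(rbind, lapply(split(results, results$value), function(d) {
    out <- data.frame(value = d$value[1])
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- mean(d[[mc]])
      out[[paste0(mc, "_sd")]] <- stats::sd(d[[mc]])
    }
    out
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$value), , drop = FALSE]
  structure(list(results = results, summary = summ, sweep = sweep,
                 path = path, config = config),
            class = "zlconn_benchmark")
}

#' @export
print.zlconn_benchmark <- function(x, ...) {
  cat(sprintf("benchmark sweep over %s (%s path), %d runs\n", x$sweep,
              x$path, nrow(x$results)))
  print(x$summary[, c("value", "auc_mean", "prs_mean", "pcc_mean")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write benchmark results as a delimited table
#'
#' @param bench a `zlconn_benchmark`.
#' @param path output TSV path.
#' @export
write_benchmark <- function(bench, path) {
  stopifnot(inherits(bench, "zlconn_benchmark"))
  utils::write.table(bench$results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
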