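# Configuration files, figure-parameter fixtures, and result serialization.

#' Load a run configuration
#'
#' Reads a YAML configuration with sections `neuron` (tau, v_th, v_re;
#' defaults 20/10/5), `drive` (kind, mu0, a_e, R_e), `inhibition`
#' (`dist` spec string and `R_i`) or `target` (`mu_T`, `sigma2`, optional
#' `drive_kind`), and optional `simulation` (n_spikes, seed, burn_in).
#' Validation errors name the offending field.
#'
#' @param path file path.
#' @return object of class `run_config` (validated list).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a raw configuration list (as from YAML).
#' @export
validate_config <- function(config) {
  nd <- config$neuron
  neuron <- lif_neuron(tau = nd$tau %||% 20,
                       v_th = nd$v_th %||% 10,
                       v_re = nd$v_re %||% 5)
  if (neuron$v_re >= neuron$v_th)
    stop("config field 'neuron$v_re' must be below v_th")
  out <- list(neuron = neuron)
  if (!is.null(config$target)) {
    tg <- config$target
    if (is.null(tg$mu_T) || is.null(tg$sigma2))
      stop("config fields 'target$mu_T' and 'target$sigma2' are required")
    out$target <- list(mu_T = tg$mu_T, sigma2 = tg$sigma2,
                       drive_kind = tg$drive_kind %||% "dc")
    if (is.null(config$inhibition$dist))
      stop("config field 'inhibition$dist' is required with a target block")
    out$dist <- parse_amp_dist(config$inhibition$dist)
  } else {
    dr <- config$drive
    if (is.null(dr)) stop("config section 'drive' (or 'target') is required")
    out$drive <- if ((dr$kind %||% "dc") == "dc") drive_dc(dr$mu0)
    else drive_shot(dr$mu0 %||% 0, dr$a_e, dr$R_e)
    inh <- config$inhibition
    if (!is.null(inh)) {
      out$dist <- parse_amp_dist(inh$dist)
      out$R_i <- inh$R_i %||% 0
    }
  }
  sim <- config$simulation
  out$simulation <- list(n_spikes = sim$n_spikes %||% 10000,
                         seed = sim$seed,
                         burn_in = sim$burn_in %||% 200)
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  lst <- list(neuron = cfg$neuron[c("tau", "v_th", "v_re")])
  if (!is.null(cfg$target)) {
    lst$target <- cfg$target
    lst$inhibition <- list(dist = amp_spec_string(cfg$dist))
  } else {
    d <- cfg$drive
    lst$drive <- if (d$kind == "dc") list(kind = "dc", mu0 = d$mu0)
    else list(kind = "shot", mu0 = d$mu0, a_e = d$a_e, R_e = d$R_e)
    if (!is.null(cfg$dist))
      lst$inhibition <- list(dist = amp_spec_string(cfg$dist), R_i = cfg$R_i)
  }
  lst$simulation <- cfg$simulation
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Build the model described by a configuration
#'
#' @param cfg a `run_config` from [load_config()].
#' @return a [shot_lif()] model.
#' @export
config_model <- function(cfg) {
  if (!is.null(cfg$target)) {
    shot_lif(cfg$dist, mu_T = cfg$target$mu_T, sigma2 = cfg$target$sigma2,
             neuron = cfg$neuron, drive_kind = cfg$target$drive_kind)
  } else {
    shot_lif(cfg$dist, drive = cfg$drive, R_i = cfg$R_i,
             neuron = cfg$neuron)
  }
}

#' Figure-parameter fixtures
#'
#' Returns the parameter grids of the reference study conditions, as
#' ready-to-run model specifications: `"fig1"` delta-amplitude neurons at
#' sub-threshold effective input; `"fig2"` the four amplitude families at
#' matched mean amplitude 1 mV (truncated Gaussian calibrated with
#' `a_p = sigma_G ~ 0.7766`, uniform on `[2 a_i, 0]`); `"fig3"` the
#' spectrum configurations; `"fig4"` truncated Gaussians of increasing
#' width at fixed peak; `"fig5"` balanced excitatory/inhibitory shot noise;
#' `"fig6"` the N = 400, K = 20 heterogeneous network.
#'
#' @param name one of `"fig1"` ... `"fig6"`.
#' @return for `"fig6"` a list of [network_config()]s; otherwise a data
#'   frame with one row per configuration and columns `dist` (spec string),
#'   `mu_T`, `sigma2`, `drive_kind`.
#' @export
fixture_suite <- function(name) {
  cc <- 0.7766
  fam4 <- c(delta = "delta:a_i=-1", uniform = "uniform:l1=-2,l2=0",
            tgauss = sprintf("tgauss:ap=-%g,sg=%g", cc, cc),
            exp = "exp:a=-1")
  switch(name,
    fig1 = {
      g <- expand.grid(dist = c("delta:a_i=-0.1", "delta:a_i=-1"),
                       sigma2 = c(0.5, 1, 2, 4),
                       stringsAsFactors = FALSE)
      data.frame(dist = g$dist, mu_T = 9, sigma2 = g$sigma2,
                 drive_kind = "dc")
    },
    fig2 = {
      g <- expand.grid(dist = unname(fam4), mu_T = c(9, 11),
                       sigma2 = c(1, 2, 4), stringsAsFactors = FALSE)
      data.frame(dist = g$dist, mu_T = g$mu_T, sigma2 = g$sigma2,
                 drive_kind = "dc")
    },
    fig3 = data.frame(
      dist = c("delta:a_i=-0.1", "delta:a_i=-1", unname(fam4)),
      mu_T = 9,
      sigma2 = c(2, 2, rep(4, 4)),
      drive_kind = "dc"),
    fig4 = {
      g <- expand.grid(sg = c(0.5, 1, 2, 5), sigma2 = c(1, 2, 4),
                       stringsAsFactors = FALSE)
      data.frame(dist = sprintf("tgauss:ap=-1,sg=%g", g$sg),
                 mu_T = 9, sigma2 = g$sigma2, drive_kind = "dc")
    },
    fig5 = {
      g <- expand.grid(dist = unname(fam4), sigma2 = c(1, 2, 4),
                       stringsAsFactors = FALSE)
      data.frame(dist = g$dist, mu_T = 9, sigma2 = g$sigma2,
                 drive_kind = "shot")
    },
    fig6 = {
      lapply(c(0.04, 0.1, 0.4, 1), function(am)
        list(dd = network_config(400, 20, amp_delta(-am)),
             ed = network_config(400, 20, amp_exponential(-am)),
             a_mean = am))
    },
    stop("unknown fixture suite: ", name))
}

#' Write a result table as annotated CSV
#'
#' Writes long-format results with `#`-prefixed header lines recording the
#' package version and, when given, the seed and a configuration digest;
#' [read_results()] inverts it.
#'
#' @param table data frame of results.
#' @param path output path.
#' @param seed,config_hash optional provenance recorded in the header.
#' @export
write_results <- function(table, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shotspike %s",
                     as.character(utils::packageVersion("shotspike"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config_hash)) writeLines(sprintf("# config: %s",
                                                config_hash), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
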