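#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages accept one integer seed; per-stage sub-seeds are
#' derived deterministically from it and a stage tag, so stages can be rerun
#' in isolation without replaying the whole stream.
#'
#' @param seed integer master seed.
#' @param tag character stage tag.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629)
}

#' Define a colour-class morphology model
#'
#' Each colour class is modelled as a bivariate lognormal over melanosome
#' (length, diameter): positive, right-skewed, with closed-form moments that
#' serve as analytic oracles in tests.
#'
#' @param colour_label class label.
#' @param log_length_mean,log_length_sd mean and sd of log length (log nm).
#' @param log_diameter_mean,log_diameter_sd mean and sd of log diameter.
#' @param corr correlation of log length and log diameter, in [-1, 1].
#' @return a \code{class_model} list.
#' @export
class_model <- function(colour_label, log_length_mean, log_length_sd,
                        log_diameter_mean, log_diameter_sd, corr = 0) {
  stopifnot(log_length_sd > 0, log_diameter_sd > 0, corr >= -1, corr <= 1)
  if (log_length_mean < log_diameter_mean)
    stop("implied median aspect ratio < 1 for class ", colour_label)
  structure(list(colour_label = colour_label,
                 log_length_mean = log_length_mean,
                 log_length_sd = log_length_sd,
                 log_diameter_mean = log_diameter_mean,
                 log_diameter_sd = log_diameter_sd,
                 corr = corr),
            class = "class_model")
}

#' Illustrative default class library
#'
#' Seven colour classes spanning the melanosome morphologies that map to
#' colour mechanism in extant birds: rod-like black, shorter brown, long
#' narrow grey, narrow rod iridescent, broad platelet iridescence, a
#' hummingbird platelet variant, and the large near-spherical penguin
#' brown-black class. Parameter values are illustrative of the nm scales
#' involved, not estimates for any real species.
#'
#' @return named list of \code{class_model}s.
#' @export
default_class_models <- function() {
  m <- list(
    class_model("black",                log(1000), 0.18, log(260), 0.16, 0.35),
    class_model("brown",                log(600),  0.22, log(230), 0.20, 0.30),
    class_model("grey",                 log(1150), 0.16, log(180), 0.15, 0.25),
    class_model("iridescent",           log(950),  0.12, log(150), 0.12, 0.20),
    class_model("platelet_iridescence", log(1450), 0.14, log(620), 0.14, 0.40),
    class_model("hummingbird_platelet", log(1100), 0.13, log(520), 0.13, 0.40),
    class_model("penguin_brown_black",  log(820),  0.15, log(700), 0.14, 0.55))
  names(m) <- vapply(m, `[[`, "", "colour_label")
  m
}

# draw n (length, diameter) pairs from a class model, rejecting draws with
# length < diameter; errors if the rejection rate is degenerate (> 99%)
draw_class <- function(model, n) {
  out_l <- numeric(0)
  out_d <- numeric(0)
  tried <- 0L
  while (length(out_l) < n) {
    k <- max(2L * (n - length(out_l)), 16L)
    z1 <- rnorm(k)
    z2 <- model$corr * z1 + sqrt(1 - model$corr^2) * rnorm(k)
    l <- exp(model$log_length_mean + model$log_length_sd * z1)
    d <- exp(model$log_diameter_mean + model$log_diameter_sd * z2)
    keep <- l >= d
    out_l <- c(out_l, l[keep])
    out_d <- c(out_d, d[keep])
    tried <- tried + k
    if (tried >= 2000L && length(out_l) < 0.01 * tried)
      stop("degenerate class specification (rejection rate > 99%): ",
           model$colour_label)
  }
  cbind(length_nm = out_l[seq_len(n)], diameter_nm = out_d[seq_len(n)])
}

#' Simulate an extant training library
#'
#' Draws per-measurement (log length, log diameter) from each class's
#' bivariate normal and exponentiates; draws violating length >= diameter
#' are rejected and redrawn. Reproducible given the seed.
#'
#' @param models list of \code{\link{class_model}}s (>= 2 classes).
#' @param n_samples_per_class samples (species patches) per class.
#' @param n_meas_per_sample measurements per sample.
#' @param seed integer seed.
#' @return measurement table (data.frame) in the standard column layout,
#'   with \code{source = "extant"} and \code{colour_label} filled in.
#' @export
simulate_library <- function(models, n_samples_per_class = 20L,
                             n_meas_per_sample = 30L, seed = 1L) {
  stopifnot(length(models) >= 2L, n_samples_per_class >= 1L,
            n_meas_per_sample >= 1L)
  set.seed(derive_seed(seed, "library"))
  rows <- list()
  for (model in models) {
    for (s in seq_len(n_samples_per_class)) {
      sid <- sprintf("%s_%02d", model$colour_label, s)
      ld <- draw_class(model, n_meas_per_sample)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid,
        taxon = sprintf("sim_%s", model$colour_label),
        source = "extant",
        body_region = "patch",
        slab_x_mm = NA_real_, slab_y_mm = NA_real_,
        colour_label = model$colour_label,
        near_body_cavity = FALSE,
        stacking_evidence = grepl("platelet", model$colour_label),
        measurement_id = seq_len(n_meas_per_sample),
        length_nm = ld[, "length_nm"],
        diameter_nm = ld[, "diameter_nm"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configure a synthetic fossil slab
#'
#' @param n_locations number of sampling locations on the slab (>= 2).
#' @param extent_mm slab extent, c(width, height) in mm.
#' @param correlation_length_mm range of the squared-exponential spatial
#'   kernel governing how quickly morphology decorrelates across the slab.
#' @param field_sd marginal sd of the spatial field on the log scale; 0
#'   switches the field off.
#' @param n_meas_per_location measurements per location.
#' @param n_platelet number of platelet-bearing locations; they are placed
#'   as a contiguous cluster (nearest locations to a random anchor),
#'   emulating platelet restriction to particular body regions.
#' @param base_class,platelet_class class labels drawn for ordinary and
#'   platelet-bearing locations.
#' @param evidence_fp_rate,evidence_fn_rate rates at which the image-evidence
#'   flag (criterion ii) disagrees with the true platelet status.
#' @param seed integer seed.
#' @return a \code{slab_config} list.
#' @export
slab_config <- function(n_locations = 53L, extent_mm = c(500, 300),
                        correlation_length_mm = 80,
                        field_sd = 0.20, n_meas_per_location = 37L,
                        n_platelet = 16L, base_class = "black",
                        platelet_class = "platelet_iridescence",
                        evidence_fp_rate = 0, evidence_fn_rate = 0,
                        seed = 1L) {
  stopifnot(n_locations >= 2L, correlation_length_mm > 0, field_sd >= 0,
            n_platelet >= 0L, n_platelet <= n_locations)
  structure(list(n_locations = as.integer(n_locations),
                 extent_mm = extent_mm,
                 correlation_length_mm = correlation_length_mm,
                 field_sd = field_sd,
                 n_meas_per_location = as.integer(n_meas_per_location),
                 n_platelet = as.integer(n_platelet),
                 base_class = base_class, platelet_class = platelet_class,
                 evidence_fp_rate = evidence_fp_rate,
                 evidence_fn_rate = evidence_fn_rate,
                 seed = as.integer(seed)),
            class = "slab_config")
}

#' Simulate a fossil slab measurement set
#'
#' Location-level mean morphology follows a spatially correlated
#' Gaussian-process-style field (squared-exponential kernel over slab
#' coordinates) added on the log scale, so nearby locations carry
#' statistically more similar nanostructures. Platelet-designated locations
#' draw from the platelet class model and carry \code{stacking_evidence}
#' (subject to the configured error rates).
#'
#' @param config \code{\link{slab_config}}.
#' @param models class model list containing \code{base_class} and
#'   \code{platelet_class}.
#' @return measurement table with \code{slab_x_mm}/\code{slab_y_mm} filled,
#'   \code{source = "fossil"}, and an attribute \code{truth}: a data.frame
#'   of per-location true platelet status.
#' @export
simulate_slab <- function(config, models = default_class_models()) {
  stopifnot(inherits(config, "slab_config"))
  stopifnot(config$base_class %in% names(models),
            config$platelet_class %in% names(models))
  set.seed(derive_seed(config$seed, "slab"))
  n <- config$n_locations
  xy <- cbind(runif(n, 0, config$extent_mm[1]),
              runif(n, 0, config$extent_mm[2]))
  # contiguous platelet patch: the n_platelet locations nearest an anchor
  is_platelet <- rep(FALSE, n)
  if (config$n_platelet > 0L) {
    anchor <- xy[sample.int(n, 1L), ]
    d_anchor <- sqrt(colSums((t(xy) - anchor)^2))
    is_platelet[order(d_anchor)[seq_len(config$n_platelet)]] <- TRUE
  }
  # spatial size field on the log scale, shared by both axes: a smooth
  # size gradient across the slab that preserves aspect ratio, so no
  # field draw can make a class geometrically degenerate
  field <- rep(0, n)
  if (config$field_sd > 0) {
    d2 <- as.matrix(dist(xy))^2
    K <- config$field_sd^2 * exp(-d2 / (2 * config$correlation_length_mm^2))
    L <- tryCatch(chol(K + diag(1e-10 * config$field_sd^2, n)),
                  error = function(e)
                    stop("spatial covariance not positive definite after jitter"))
    field <- drop(crossprod(L, rnorm(n)))
  }
  evidence <- is_platelet
  flip_fp <- runif(n) < config$evidence_fp_rate
  flip_fn <- runif(n) < config$evidence_fn_rate
  evidence[!is_platelet & flip_fp] <- TRUE
  evidence[is_platelet & flip_fn] <- FALSE
  regions_p <- c("head", "neck", "chest")
  regions_b <- c("back", "wing", "tail", "leg")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    base <- models[[if (is_platelet[i]) config$platelet_class else
      config$base_class]]
    local_model <- base
    local_model$log_length_mean <- base$log_length_mean + field[i]
    local_model$log_diameter_mean <- base$log_diameter_mean + field[i]
    ld <- draw_class(local_model, config$n_meas_per_location)
    rows[[i]] <- data.frame(
      sample_id = sprintf("slab_%02d", i),
      taxon = "fossil_taxon",
      source = "fossil",
      body_region = if (is_platelet[i]) regions_p[1L + i %% 3L] else
        regions_b[1L + i %% 4L],
      slab_x_mm = xy[i, 1], slab_y_mm = xy[i, 2],
      colour_label = "unknown",
      near_body_cavity = FALSE,
      stacking_evidence = evidence[i],
      measurement_id = seq_len(config$n_meas_per_location),
      length_nm = ld[, "length_nm"],
      diameter_nm = ld[, "diameter_nm"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    sample_id = sprintf("slab_%02d", seq_len(n)),
    is_platelet = is_platelet,
    stringsAsFactors = FALSE)
  out
}
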