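#' Built-in planted response templates
#'
#' Multiplicative per-group effect vectors emulating the response classes the
#' screening is meant to recover. Dragonfly-specific genes respond strongly
#' (8-fold) under continuous dragonfly exposure, return essentially to the
#' control level when the predator is removed (1.1-fold residual, well inside
#' the 2-fold no-change band), and show only a mild opposite-direction
#' response to the other predator. Salamander-specific genes mirror this.
#' Common genes respond 8-fold to both predators and keep a strong,
#' non-reverting removal residual; half the panel carries it mainly after
#' dragonfly removal and half after salamander removal, the kind of
#' per-gene asymmetry real response panels show (e.g. a gene responding
#' 8.5-fold to continuous exposure with a 4.3-fold removal residual).
#'
#' @param fold Planted effect size for the responsive groups (default 8).
#' @return Named list of templates; each is a list with `label`, `count`, and
#'   `effects` (named positive multiplier per treatment group).
#' @export
default_templates <- function(fold = 8) {
  eff <- function(drago, salam, minus_drago, minus_salam) {
    c(Cont = 1, Drago = drago, Salam = salam,
      MinusDrago = minus_drago, MinusSalam = minus_salam)
  }
  list(
    dragonfly_specific = list(
      label = "dragonfly_specific", count = 13,
      effects = eff(fold, 1 / 1.5, 1.1, 1 / 1.1)
    ),
    salamander_specific = list(
      label = "salamander_specific", count = 9,
      effects = eff(1 / 1.5, fold, 1 / 1.1, 1.1)
    ),
    common_drago_residual = list(
      label = "common", count = 8,
      effects = eff(fold, fold, 4, 1.5)
    ),
    common_salam_residual = list(
      label = "common", count = 8,
      effects = eff(fold, fold, 1.5, 4)
    )
  )
}

#' Describe a synthetic predator-exposure study
#'
#' Captures the study design the generator reproduces: five treatment groups
#' hybridized in triplicate, a 15611-probe array including AFFX-style control
#' probes, log-normal probe noise, and planted response templates.
#'
#' @param n_probes Total probes on the array, control probes included
#'   (default 15611).
#' @param n_replicates Chips per group (default 3).
#' @param n_control_probes Probes given the `AFFX` prefix and no treatment
#'   effect (default 50).
#' @param baseline_mean,baseline_sd Hyperprior for each probe's baseline log2
#'   level (defaults 7 and 1.5, a typical MAS5 dynamic range).
#' @param noise_sd Per-observation log2 noise SD (default 0.25).
#' @param templates Planted templates as from [default_templates()]; use
#'   `list()` for a fully null array.
#' @param seed Integer seed driving all randomness (default 1).
#' @return A `scenario` list.
#' @export
predation_scenario <- function(n_probes = 15611, n_replicates = 3,
                               n_control_probes = 50,
                               baseline_mean = 7, baseline_sd = 1.5,
                               noise_sd = 0.25,
                               templates = default_templates(),
                               seed = 1) {
  n_planted <- sum(vapply(templates, function(t) t$count, numeric(1)))
  if (n_planted + n_control_probes > n_probes) {
    stop("templates plus control probes exceed n_probes", call. = FALSE)
  }
  for (t in templates) {
    if (any(t$effects <= 0)) stop("template effects must be positive", call. = FALSE)
    if (!setequal(names(t$effects), predation_groups)) {
      stop("template effects must be named by the five groups", call. = FALSE)
    }
  }
  structure(list(n_probes = n_probes, n_replicates = n_replicates,
                 n_control_probes = n_control_probes,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, templates = templates, seed = seed),
            class = "scenario")
}

#' Generate a synthetic predator-exposure dataset
#'
#' Per probe `i` on chip `j` of group `g`, the linear signal is
#' `2^(mu_i + log2(effect_i[g]) + eps_ij)` with `eps ~ Normal(0, noise_sd)`
#' and `mu_i` drawn from the baseline hyperprior. Control probes carry no
#' treatment effect, so all successfully hybridized chips share their
#' control-probe profile up to noise. Output is bit-reproducible given the
#' scenario seed.
#'
#' @param scenario A [predation_scenario()].
#' @return A list: `matrix` (linear-scale [expression_matrix()] with design
#'   attached), `design`, `annotation`, and `truth` (tibble of each probe's
#'   planted label and per-group effects).
#' @export
simulate_predation <- function(scenario = predation_scenario()) {
  stopifnot(inherits(scenario, "scenario"))
  s <- scenario
  design <- tibble::tibble(
    sample_id = unlist(lapply(predation_groups, function(g)
      paste0(g, "_", seq_len(s$n_replicates)))),
    group = rep(predation_groups, each = s$n_replicates)
  )
  design <- validate_design(design)
  n_chip <- nrow(design)

  n_planted <- sum(vapply(s$templates, function(t) t$count, numeric(1)))
  n_null <- s$n_probes - s$n_control_probes - n_planted
  labels <- c(rep("control", s$n_control_probes),
              unlist(lapply(s$templates, function(t) rep(t$label, t$count))),
              rep("null", n_null))
  ids <- character(s$n_probes)
  ids[labels == "control"] <- sprintf("AFFX-ctrl-%02d_at", seq_len(s$n_control_probes))
  planted_idx <- which(!labels %in% c("control", "null"))
  ids[planted_idx] <- sprintf("Xp.%04d.1.S1_at", seq_along(planted_idx))
  null_idx <- which(labels == "null")
  ids[null_idx] <- sprintf("Xn.%05d.1.A1_at", seq_along(null_idx))

  effects <- matrix(1, s$n_probes, length(predation_groups),
                    dimnames = list(ids, predation_groups))
  row0 <- s$n_control_probes
  for (t in s$templates) {
    rows <- row0 + seq_len(t$count)
    effects[rows, ] <- matrix(t$effects[predation_groups], t$count,
                              length(predation_groups), byrow = TRUE)
    row0 <- row0 + t$count
  }

  withr::with_seed(s$seed, {
    mu <- stats::rnorm(s$n_probes, s$baseline_mean, s$baseline_sd)
    eps <- matrix(stats::rnorm(s$n_probes * n_chip, 0, s$noise_sd),
                  s$n_probes, n_chip)
  })
  log2_effect <- log2(effects[, design$group, drop = FALSE])
  vals <- 2^(mu + log2_effect + eps)
  dimnames(vals) <- list(ids, design$sample_id)
  em <- join_design(expression_matrix(vals, is_log = FALSE), design)

  truth <- tibble::tibble(probe_id = ids, label = labels) |>
    dplyr::bind_cols(tibble::as_tibble(effects) |>
                       stats::setNames(paste0("effect_", predation_groups)))
  annotation <- tibble::tibble(
    probe_id = ids,
    gene_symbol = dplyr::case_when(
      labels == "control" ~ paste0("AFFX_", seq_len(s$n_probes)),
      labels == "null" ~ NA_character_,
      TRUE ~ sprintf("gene%04d", seq_len(s$n_probes))
    ),
    gene_title = ifelse(labels %in% c("control", "null"), NA_character_,
                        paste("synthetic planted response gene, class", labels)),
    accession = NA_character_
  )
  list(matrix = em, design = design, annotation = annotation, truth = truth)
}

#' Plant a hybridization failure on one chip
#'
#' Replaces the chosen chip's control-probe signals with independent draws
#' from the baseline hyperprior, so the chip's control profile no longer
#' correlates with its peers and [qc_control_probes()] flags it at the
#' default threshold.
#'
#' @param sim Simulation list from [simulate_predation()] (or any
#'   `expression_matrix`).
#' @param chip Sample ID of the chip to fail (e.g. `"Cont_1"`).
#' @param seed Integer seed for the replacement draws.
#' @param control_prefix Control-probe prefix (default `"AFFX"`).
#' @param baseline_mean,baseline_sd Hyperprior for the replacement profile.
#' @return The input with the chip's control probes randomized (same type as
#'   the input).
#' @export
plant_chip_failure <- function(sim, chip, seed = 1, control_prefix = "AFFX",
                               baseline_mean = 7, baseline_sd = 1.5) {
  em <- if (inherits(sim, "expression_matrix")) sim else sim$matrix
  if (!chip %in% sample_ids(em)) {
    stop("unknown chip ", sQuote(chip), call. = FALSE)
  }
  is_ctrl <- startsWith(probe_ids(em), control_prefix)
  if (!any(is_ctrl)) stop("no control probes with prefix ", sQuote(control_prefix),
                          call. = FALSE)
  vals <- em$values
  withr::with_seed(seed, {
    vals[is_ctrl, chip] <- 2^stats::rnorm(sum(is_ctrl), baseline_mean, baseline_sd)
  })
  out <- expression_matrix(vals, is_log = em$is_log, design = em$design)
  if (inherits(sim, "expression_matrix")) out else { sim$matrix <- out; sim }
}
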