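# Seeded generators reproducing the statistical structure the pipeline
# assumes: Gaussian binding energies, uniform heavy-atom counts, Gaussian
# logP, a configurable fraction of rule-failing descriptor pairs, additive
# adduct stabilization terms and Gaussian coordinate jitter. Each generator
# is a pure function of its spec (root seed included); stage-specific RNG
# streams are derived from the root seed so the library, trajectory and
# adduct generators do not share a stream.

derive_seed <- function(seed, stage) {
  # keep derived seeds positive and below 2^31
  (as.numeric(seed) * 48271 + stage) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic compound library
#'
#' Defaults emulate a ~237-compound docking screen whose energies span about
#' -5.9 to -8.8 kcal/mol: Gaussian binding energies centred at -7 kcal/mol
#' with sd 1, heavy-atom counts uniform on 13-38, Gaussian logP, and a small
#' fraction of compounds planted in the Pfizer-rejection region.
#'
#' @param n_compounds library size (>= 1).
#' @param be_mean,be_sd binding-energy distribution (kcal/mol).
#' @param ha_range inclusive heavy-atom count range, within \[1, 200\].
#' @param logp_mean,logp_sd logP distribution.
#' @param fraction_rule_failures fraction in \[0, 1\] given a
#'   (logP > 3, TPSA < 75) descriptor pair.
#' @param planted_hit optional list with `id` and `be_margin` (kcal/mol); the
#'   planted compound gets binding energy (library minimum - be_margin) and
#'   all-rule-passing descriptors.
#' @param seed integer root seed.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(n_compounds = 237, be_mean = -7, be_sd = 1,
                         ha_range = c(13, 38), logp_mean = 2.5, logp_sd = 0.8,
                         fraction_rule_failures = 0.1, planted_hit = NULL,
                         seed = 1) {
  stopifnot(n_compounds >= 1, be_sd >= 0, logp_sd >= 0,
            length(ha_range) == 2, ha_range[1] >= 1, ha_range[2] <= 200,
            ha_range[1] <= ha_range[2],
            fraction_rule_failures >= 0, fraction_rule_failures <= 1)
  if (!is.null(planted_hit)) {
    stopifnot(is.list(planted_hit), !is.null(planted_hit$id),
              is.numeric(planted_hit$be_margin), planted_hit$be_margin >= 0)
  }
  structure(list(n_compounds = n_compounds, be_mean = be_mean, be_sd = be_sd,
                 ha_range = ha_range, logp_mean = logp_mean, logp_sd = logp_sd,
                 fraction_rule_failures = fraction_rule_failures,
                 planted_hit = planted_hit, seed = seed),
            class = "library_spec")
}

#' Generate a synthetic compound library
#'
#' Draws binding energies, sizes and descriptors per the spec. Descriptors
#' are constructed to pass the Lipinski and Pfizer rules except for the
#' requested fraction, which receives a Pfizer-failing (logP > 3, TPSA < 75)
#' pair. The planted hit, when present, is assigned a binding energy
#' `be_margin` below the library minimum and rule-passing descriptors, so it
#' survives every stage and tops any binding-energy ranking by construction.
#' Identical specs (seed included) give identical output.
#'
#' @param spec a [library_spec()].
#' @return list with `compounds` (id/role), `scores` (id/binding_energy),
#'   `profiles` (descriptors, suitable for [run_funnel()]), and the spec.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    n <- spec$n_compounds
    ids <- sprintf("S%04d", seq_len(n))
    be <- stats::rnorm(n, spec$be_mean, spec$be_sd)
    ha <- sample(seq(spec$ha_range[1], spec$ha_range[2]), n, replace = TRUE)
    logp <- stats::rnorm(n, spec$logp_mean, spec$logp_sd)
    tpsa <- stats::runif(n, 80, 140) # bulk sits above the Pfizer TPSA bound
    mw <- pmin(14 * ha + stats::rnorm(n, 20, 5), 500)
    n_hba <- sample(2:8, n, replace = TRUE)
    n_hbd <- sample(0:4, n, replace = TRUE)
    n_fail <- round(spec$fraction_rule_failures * n)
    if (n_fail > 0) {
      fail_idx <- sample(n, n_fail)
      logp[fail_idx] <- stats::runif(n_fail, 3.2, 4.5)
      tpsa[fail_idx] <- stats::runif(n_fail, 40, 70)
    }
    if (!is.null(spec$planted_hit)) {
      ids[1] <- spec$planted_hit$id
      be[1] <- min(be) - spec$planted_hit$be_margin
      ha[1] <- round(mean(spec$ha_range))
      logp[1] <- 2.0
      tpsa[1] <- 90
      mw[1] <- 350
      n_hba[1] <- 4
      n_hbd[1] <- 2
    }
    list(
      compounds = tibble::tibble(compound_id = ids, role = "analog"),
      scores = tibble::tibble(compound_id = ids, binding_energy = be,
                              source = "other"),
      profiles = tibble::tibble(compound_id = ids, mw = mw, heavy_atoms = ha,
                                n_hba = n_hba, n_hbd = n_hbd, tpsa = tpsa,
                                logp = logp),
      spec = spec
    )
  })
}

#' Specification of a synthetic trajectory
#'
#' @param n_atoms number of atoms (>= 3).
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing in ps.
#' @param fluctuation_sd per-coordinate Gaussian jitter sd (nm).
#' @param rigid_motion optional list with `rotation_rate` (degrees/ps about
#'   the z axis) and `translation_rate` (nm/ps along the box diagonal).
#' @param seed integer root seed.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_atoms = 50, n_frames = 100, dt = 1,
                            fluctuation_sd = 0.05, rigid_motion = NULL,
                            seed = 1) {
  stopifnot(n_atoms >= 3, n_frames >= 2, dt > 0, fluctuation_sd >= 0)
  structure(list(n_atoms = n_atoms, n_frames = n_frames, dt = dt,
                 fluctuation_sd = fluctuation_sd, rigid_motion = rigid_motion,
                 seed = seed),
            class = "trajectory_spec")
}

rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate a synthetic trajectory
#'
#' A reference structure is drawn once (uniform in a 3 nm box); each frame is
#' the reference under optional rigid motion (rotation about z plus uniform
#' translation, growing linearly in time) with i.i.d. Gaussian jitter of the
#' requested sd added to every coordinate. With zero jitter the series is
#' pure rigid motion, which optimal superposition removes exactly.
#'
#' @param spec a [trajectory_spec()].
#' @return a [trajectory()].
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  with_seed(derive_seed(spec$seed, 2L), {
    ref <- matrix(stats::runif(spec$n_atoms * 3, 0, 3), ncol = 3)
    times <- (seq_len(spec$n_frames) - 1) * spec$dt
    frames <- lapply(times, function(t) {
      xyz <- ref
      if (!is.null(spec$rigid_motion)) {
        xyz <- xyz %*% rotation_z(spec$rigid_motion$rotation_rate * t)
        shift <- spec$rigid_motion$translation_rate * t / sqrt(3)
        xyz <- xyz + matrix(shift, nrow(xyz), 3)
      }
      if (spec$fluctuation_sd > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$fluctuation_sd),
                            ncol = 3)
      }
      structure_frame(xyz)
    })
    trajectory(frames, times)
  })
}

#' Generate synthetic component/adduct energy tables
#'
#' Component and peptide energies are drawn around magnitudes typical of
#' electrostatic-potential-energy tables; the adduct energy is their sum plus
#' an additive stabilization term Delta ~ Normal(stabilization_mean, sd), so
#' [adduct_stabilization()] recovers each Delta exactly.
#'
#' @param n number of adducts (>= 1).
#' @param stabilization_mean,stabilization_sd distribution of the additive
#'   stabilization term (kcal/mol; negative mean = stabilizing).
#' @param seed integer root seed.
#' @return tibble with `id`, `e_compound`, `e_peptide`, `e_adduct`,
#'   `delta_true`.
#' @export
generate_adduct_energies <- function(n, stabilization_mean = -50,
                                     stabilization_sd = 5, seed = 1) {
  stopifnot(n >= 1, stabilization_sd >= 0)
  with_seed(derive_seed(seed, 3L), {
    e_compound <- stats::rnorm(n, -46, 2)
    e_peptide <- stats::rnorm(n, -62, 2)
    delta <- stats::rnorm(n, stabilization_mean, stabilization_sd)
    tibble::tibble(id = sprintf("adduct%04d", seq_len(n)),
                   e_compound = e_compound, e_peptide = e_peptide,
                   e_adduct = e_compound + e_peptide + delta,
                   delta_true = delta)
  })
}
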