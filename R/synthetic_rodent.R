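#' Simulate a rodent cohort at the measurement level
#'
#' Draws per-vessel compartment intensities (perivascular endfoot,
#' perivascular astrocyte, neuropil) for a cohort of animals, from the same
#' generative model the scene renderer plants: compartment baselines scaled
#' by per-group multipliers, an astrocyte amplitude growing with vessel
#' diameter, a per-animal random intercept for each compartment, and
#' residual per-vessel noise. This is the replicated-simulation engine for
#' power and type-I studies of the nested (vessels-within-animals) designs;
#' recovery of these same quantities from rendered images is validated
#' separately at small n.
#'
#' @param groups data.frame with columns `label`, `n_animals`, and the
#'   multipliers `endfoot_mul`, `astro_mul`, `neuropil_mul` (1 = baseline).
#' @param vessels_per_animal vessels measured per animal (default 15).
#' @param baseline named compartment baselines in AU
#'   (default endfoot 200, astro 120, neuropil 80).
#' @param astro_diameter_slope astrocyte AU per um of diameter; may be a
#'   named vector (one slope per group label) to plant slope differences.
#' @param diameter_range_um uniform diameter range of the sampled vessels.
#' @param animal_sd between-animal SD (AU, per compartment).
#' @param residual_sd per-vessel residual SD (AU).
#' @param seed RNG seed.
#' @return data.frame: `group`, `animal`, `vessel`, `diameter_um`,
#'   `pv_endfoot_if`, `pv_astro_if`, `neuropil_if`.
#' @export
simulate_rodent_cohort <- function(groups, vessels_per_animal = 15,
                                   baseline = c(endfoot = 200, astro = 120,
                                                neuropil = 80),
                                   astro_diameter_slope = 0,
                                   diameter_range_um = c(12, 40),
                                   animal_sd = 8, residual_sd = 15,
                                   seed = 1L) {
  stopifnot(all(c("label", "n_animals", "endfoot_mul", "astro_mul",
                  "neuropil_mul") %in% names(groups)))
  if (length(astro_diameter_slope) == 1L && is.null(names(astro_diameter_slope))) {
    astro_diameter_slope <- stats::setNames(
      rep(astro_diameter_slope, nrow(groups)), groups$label)
  }
  with_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      slope <- astro_diameter_slope[[as.character(g$label)]]
      for (a in seq_len(g$n_animals)) {
        u <- stats::rnorm(3, 0, animal_sd)  # per-compartment animal intercepts
        nv <- vessels_per_animal
        diam <- stats::runif(nv, diameter_range_um[1L], diameter_range_um[2L])
        rows[[length(rows) + 1L]] <- data.frame(
          group = g$label,
          animal = sprintf("%s_%02d", g$label, a),
          vessel = seq_len(nv),
          diameter_um = diam,
          pv_endfoot_if = pmax(baseline[["endfoot"]] * g$endfoot_mul + u[1L] +
                                 stats::rnorm(nv, 0, residual_sd), 0),
          pv_astro_if = pmax(baseline[["astro"]] * g$astro_mul + slope * diam +
                               u[2L] + stats::rnorm(nv, 0, residual_sd), 0),
          neuropil_if = pmax(baseline[["neuropil"]] * g$neuropil_mul + u[3L] +
                               stats::rnorm(nv, 0, residual_sd), 0))
      }
    }
    do.call(rbind, rows)
  })
}

#' Pool nested vessel measures two ways
#'
#' The nested designs are reported both as "all vessels" (every vessel one
#' observation) and as "per animal" (animal means). Both poolings are
#' returned; their grand means agree exactly when the design is balanced.
#'
#' @param df output of [simulate_rodent_cohort()] (or any data.frame with
#'   `group`, `animal` and the measure column).
#' @param measure column name to pool.
#' @return list: `all_vessels` (data.frame `group`, `animal`, `value`),
#'   `per_animal` (data.frame `group`, `animal`, `value` = animal mean),
#'   `grand_means` (per-group means under both poolings).
#' @export
pool_vessel_measures <- function(df, measure) {
  stopifnot(measure %in% names(df))
  all_vessels <- data.frame(group = df$group, animal = df$animal,
                            value = df[[measure]])
  per_animal <- stats::aggregate(value ~ group + animal, data = all_vessels,
                                 FUN = mean)
  gm <- merge(
    stats::setNames(stats::aggregate(value ~ group, all_vessels, mean),
                    c("group", "all_vessels")),
    stats::setNames(stats::aggregate(value ~ group, per_animal, mean),
                    c("group", "per_animal")))
  list(all_vessels = all_vessels, per_animal = per_animal, grand_means = gm)
}
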