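# Synthetic cohort generation. Vessels are single-lesion (occasionally
# serial-lesion) coronary trees with a main vessel and two side branches,
# built to the structure of an FFR-guided PCI study population: target
# vessels with invasive pre-intervention FFR at or below 0.8 (enforced by
# rejection sampling, mirroring study screening), a LAD-dominant vessel
# mix, and noisy "invasive" measurements whose noise SD is sized so the
# simulated Bland-Altman limits of agreement match those reported for
# FFR-CT validation. The ground truth behind the invasive post-PCI value
# is the model FFR of the clinician-stented (non-blinded) geometry, so the
# non-blinded arm is by construction closer to truth than the blinded arm.

#' Cohort generator configuration
#'
#' Defaults encode the emulated study conditions: 78 vessels, vessel-type
#' mix LAD 58/78, LCX 7/78, RCA 13/78, inclusion at invasive pre-PCI FFR
#' <= 0.8, measurement noise SDs 0.077 (pre) and 0.037 (post) sized to
#' limits of agreement of about +/-0.151 and +/-0.072, a 1:2
#' discovery/validation split, and clinician stent-plan perturbations
#' whose upward length bias targets a median actual:planned length ratio
#' of about 26.5/23.
#'
#' @param n_vessels number of vessels to generate (default 78)
#' @param seed integer seed for the single RNG stream
#' @param vessel_mix named probabilities for LAD/LCX/RCA
#' @param pct_ds_range uniform range of percent diameter stenosis
#' @param lesion_length_meanlog,lesion_length_sdlog lognormal lesion
#'   length parameters (mm); the default median is 20 mm
#' @param lesion_length_range truncation bounds for lesion length (mm)
#' @param serial_prob probability of a second, serial lesion
#' @param sigma_pre,sigma_post invasive measurement noise SDs
#' @param ffr_inclusion_max inclusion threshold on invasive pre-PCI FFR
#' @param length_up_prob,length_up2_prob clinician probability of choosing
#'   the next / second-next catalog length above the planned one
#' @param center_jitter_sd SD of clinician stent-center jitter (mm)
#' @param diameter_up_prob clinician probability of one catalog diameter
#'   step up
#' @param split_ratio discovery:validation ratio, default `c(1, 2)`
#' @param vm_mean,vm_sd,vm_range myocardial volume distribution (mL)
#' @param hyperemia_factor outlet resistance multiplier under hyperemia
#' @param mean_aortic_pressure resting mean aortic pressure (mmHg)
#' @param keep_trees keep the generated trees and plans in the result
#'   (memory-heavy for large cohorts)
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_vessels = 78L, seed = 1L,
                          vessel_mix = c(LAD = 58 / 78, LCX = 7 / 78,
                                         RCA = 13 / 78),
                          pct_ds_range = c(30, 60),
                          lesion_length_meanlog = log(20),
                          lesion_length_sdlog = 0.35,
                          lesion_length_range = c(5, 50),
                          serial_prob = 0.10,
                          sigma_pre = 0.077, sigma_post = 0.037,
                          ffr_inclusion_max = 0.8,
                          length_up_prob = 0.55, length_up2_prob = 0.15,
                          center_jitter_sd = 1.0, diameter_up_prob = 0.2,
                          split_ratio = c(1, 2),
                          vm_mean = 120, vm_sd = 25, vm_range = c(70, 200),
                          hyperemia_factor = 0.24,
                          mean_aortic_pressure = 93,
                          keep_trees = FALSE) {
  if (abs(sum(vessel_mix) - 1) > 1e-9)
    stop_ffrct("vessel_mix probabilities must sum to 1", class = "ffrct_config_error")
  if (sigma_pre < 0 || sigma_post < 0)
    stop_ffrct("noise SDs must be non-negative", class = "ffrct_config_error")
  if (n_vessels < 3)
    stop_ffrct("n_vessels must be at least 3", class = "ffrct_config_error")
  structure(as.list(environment()), class = "cohort_config")
}

runif_trunc <- function(n, range) stats::runif(n, range[1], range[2])

rnorm_trunc <- function(mean, sd, range) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  mean
}

rlnorm_trunc <- function(meanlog, sdlog, range) {
  for (i in 1:100) {
    x <- stats::rlnorm(1, meanlog, sdlog)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  exp(meanlog)
}

# cosine narrowing multiplier applied to the native lumen over [a, b]
apply_narrowing <- function(d, s, a, b, depth) {
  inside <- s >= a & s <= b
  d[inside] <- d[inside] *
    (1 - depth * (1 - cos(2 * pi * (s[inside] - a) / (b - a))) / 2)
  d
}

#' Generate one synthetic lesioned vessel
#'
#' Draws a vessel label from the configured mix, builds a tapered main
#' vessel (proximal diameter about 3.5 mm for LAD/RCA and 3.0 mm for LCX)
#' with two side branches, superimposes one (occasionally two serial)
#' cosine-shaped narrowings distal to the second branch, and samples the
#' myocardial volume. Deterministic given the RNG state.
#'
#' @param config a [cohort_config()]
#' @return list with `tree` (a [coronary_tree()]), `label`, and
#'   `lesion_truth` (data frame of the injected narrowings)
#' @export
generate_vessel <- function(config = cohort_config()) {
  label <- sample(names(config$vessel_mix), 1, prob = config$vessel_mix)
  d0 <- switch(label, LAD = 3.5, RCA = 3.5, LCX = 3.0) + stats::rnorm(1, 0, 0.15)
  d0 <- max(d0, 2.8)
  main_len <- stats::runif(1, 95, 115)
  taper_ratio <- stats::runif(1, 0.68, 0.78)   # distal/proximal diameter
  lambda <- -log(taper_ratio) / main_len
  # target-vessel exclusion: keep the native lumen of the stentable region
  # (lesions end 12 mm short of the distal end) above 2.25 mm
  lambda <- min(lambda, log(d0 / 2.3) / (main_len - 12))
  s <- seq(0, main_len, by = 1)
  if (s[length(s)] < main_len) s <- c(s, main_len)
  d_native <- d0 * exp(-lambda * s)

  b1 <- stats::runif(1, 25, 35)
  b2 <- stats::runif(1, 50, 60)

  # lesion(s) distal to the second branch, clear of the ends
  lesions <- list()
  len1 <- rlnorm_trunc(config$lesion_length_meanlog,
                       config$lesion_length_sdlog,
                       config$lesion_length_range)
  lo <- b2 + 6
  hi <- main_len - 12
  len1 <- min(len1, hi - lo - 2)
  a1 <- stats::runif(1, lo, hi - len1)
  depth1 <- runif_trunc(1, config$pct_ds_range) / 100
  d_les <- apply_narrowing(d_native, s, a1, a1 + len1, depth1)
  lesions[[1]] <- data.frame(s_start = a1, s_end = a1 + len1,
                             pct_ds = 100 * depth1)
  if (stats::runif(1) < config$serial_prob) {
    gap <- stats::runif(1, 3, 8)
    len2 <- stats::runif(1, 5, 12)
    a2 <- a1 + len1 + gap
    if (a2 + len2 <= hi) {
      depth2 <- 0.8 * depth1
      d_les <- apply_narrowing(d_les, s, a2, a2 + len2, depth2)
      lesions[[2]] <- data.frame(s_start = a2, s_end = a2 + len2,
                                 pct_ds = 100 * depth2)
    }
  }

  branch_profile <- function(attach_s) {
    dl <- d0 * exp(-lambda * attach_s) * stats::runif(1, 0.5, 0.62)
    blen <- stats::runif(1, 20, 30)
    sb <- seq(0, blen, by = 1)
    if (sb[length(sb)] < blen) sb <- c(sb, blen)
    centerline_profile(sb, dl * exp(-0.003 * sb) / 2)
  }
  segs <- list(
    main = list(profile = centerline_profile(s, d_les / 2), parent = NULL,
                label = label),
    side1 = list(profile = branch_profile(b1), parent = "main",
                 branch_s_mm = b1, label = "other"),
    side2 = list(profile = branch_profile(b2), parent = "main",
                 branch_s_mm = b2, label = "other"))
  vm <- rnorm_trunc(config$vm_mean, config$vm_sd, config$vm_range)
  tree <- coronary_tree(segs, inlet = "main", myocardial_volume_ml = vm)
  list(tree = tree, label = label,
       lesion_truth = do.call(rbind, lesions))
}

#' Simulate an invasive FFR measurement
#'
#' Adds Gaussian measurement noise to a true FFR and clips the result to
#' (0.05, 1]. The default SDs in [cohort_config()] (0.077 pre, 0.037
#' post) are sized so simulated Bland-Altman 95% limits of agreement are
#' about +/-1.96 sigma, i.e. +/-0.151 and +/-0.072.
#'
#' @param ffr_truth true FFR values in (0, 1]
#' @param sigma measurement noise SD, >= 0
#' @return noisy FFR values, same length
#' @export
simulate_invasive <- function(ffr_truth, sigma) {
  if (any(ffr_truth <= 0 | ffr_truth > 1))
    stop_ffrct("true FFR must lie in (0, 1]", class = "ffrct_config_error")
  if (sigma < 0)
    stop_ffrct("sigma must be non-negative", class = "ffrct_config_error")
  if (sigma == 0) return(ffr_truth)
  pmin(1, pmax(0.05, ffr_truth + stats::rnorm(length(ffr_truth), 0, sigma)))
}

#' Perturb a blinded stent plan the way an operator would
#'
#' Re-draws each stent length from the catalog with an upward bias
#' (operators tend to size up for full coverage), jitters the stent
#' center, and occasionally steps the diameter up one catalog size. With
#' all perturbation scales zero the blinded plan is returned unchanged.
#' A perturbed stent that would leave its segment is re-drawn (bounded
#' retries), falling back to the blinded geometry.
#'
#' @param plans list of blinded [stent_plan()]s
#' @param tree the [coronary_tree()] the plans apply to
#' @param config a [cohort_config()]
#' @param catalog a [stent_catalog()]
#' @param blend_length blend length used for fit checking (mm)
#' @return list of [stent_plan()]s with mode `"non_blinded"`
#' @export
emulate_clinician_plan <- function(plans, tree, config = cohort_config(),
                                   catalog = stent_catalog(),
                                   blend_length = 1) {
  if (inherits(plans, "stent_plan")) plans <- list(plans)
  lapply(plans, function(p) {
    prof <- tree$segments[[p$segment_id]]$profile
    s_lo <- prof$s_mm[1]
    s_hi <- prof$s_mm[length(prof$s_mm)]
    lens <- catalog$lengths_mm
    i0 <- which.min(abs(lens - p$length))
    for (try in 1:10) {
      u <- stats::runif(1)
      step <- if (u < config$length_up2_prob) 2L
              else if (u < config$length_up2_prob + config$length_up_prob) 1L
              else 0L
      len <- lens[min(length(lens), i0 + step)]
      center <- p$center_s + stats::rnorm(1, 0, config$center_jitter_sd)
      dia <- p$d_prox
      if (stats::runif(1) < config$diameter_up_prob) {
        ds <- catalog$diameters_mm
        dia <- ds[min(length(ds), which.min(abs(ds - dia)) + 1L)]
      }
      if (center - len / 2 - blend_length >= s_lo &&
          center + len / 2 + blend_length <= s_hi) {
        return(stent_plan(p$segment_id, center, len, dia,
                          max(p$d_dist, dia * (p$d_dist / p$d_prox)),
                          mode = "non_blinded"))
      }
    }
    stent_plan(p$segment_id, p$center_s, p$length, p$d_prox, p$d_dist,
               mode = "non_blinded")
  })
}

#' Generate a full synthetic cohort
#'
#' For each vessel: build the geometry, compute the model (FFR-CT) pre-PCI
#' FFR at the distal lesion reference site with the reduced-order solver
#' under hyperemic outlet conditions, simulate the invasive pre-PCI
#' measurement and reject vessels above the inclusion threshold; plan
#' blinded stents from the FFR profile and detected lesions, apply them
#' and recompute FFR; perturb the plan into the clinician (non-blinded)
#' arm, apply and recompute; simulate the invasive post-PCI measurement
#' from the clinician-stented model truth. Finally assign the
#' discovery/validation split by a seeded permutation at the exact
#' configured ratio.
#'
#' @param config a [cohort_config()]
#' @return object of class `ffr_cohort`: a list with `records` (one row
#'   per vessel), `config`, and (if `keep_trees`) `trees` and `plans`
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  catalog <- stent_catalog()
  recs <- list()
  trees <- list()
  plansets <- list()
  attempts <- 0L
  max_attempts <- 40L * config$n_vessels
  while (length(recs) < config$n_vessels) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_ffrct(paste0("rejection rate above 95%%: the severity distribution ",
                        "is inconsistent with the inclusion criterion"),
                 class = "ffrct_config_error")
    vs <- generate_vessel(config)
    rec <- tryCatch(
      simulate_vessel_record(vs, config, catalog),
      ffrct_error = function(e) NULL)
    if (is.null(rec)) next
    if (rec$row$ffr_invasive_pre > config$ffr_inclusion_max) next
    rec$row$id <- sprintf("v%03d", length(recs) + 1L)
    recs[[length(recs) + 1L]] <- rec$row
    if (config$keep_trees) {
      trees[[rec$row$id]] <- vs$tree
      plansets[[rec$row$id]] <- rec$plans
    }
  }
  records <- do.call(rbind, recs)
  n <- nrow(records)
  n_disc <- round(n * config$split_ratio[1] / sum(config$split_ratio))
  cohort <- rep("validation", n)
  cohort[sample.int(n, n_disc)] <- "discovery"
  records$cohort <- cohort
  records <- records[, c("id", setdiff(names(records), "id"))]
  rownames(records) <- NULL
  out <- list(records = records, config = config, attempts = attempts)
  if (config$keep_trees) {
    out$trees <- trees
    out$plans <- plansets
  }
  class(out) <- "ffr_cohort"
  out
}

# one vessel through the full measurement pipeline
simulate_vessel_record <- function(vs, config, catalog) {
  tree <- vs$tree
  props <- blood_properties()
  inflow <- inflow_model(tree$myocardial_volume_ml,
                         mean_aortic_pressure = config$mean_aortic_pressure)
  outlets <- assign_outlets(tree, inflow, props,
                            hyperemia_factor = config$hyperemia_factor)
  sol_pre <- solve_steady(tree, outlets, inflow$qbar_ml_s, props)
  les <- detect_lesions(tree)
  les <- les[les$segment_id == "main", , drop = FALSE]
  if (nrow(les) == 0L)
    stop_ffrct("no detectable lesion", class = "ffrct_config_error")
  site_s <- min(max(les$s_end) + 5,
                profile_length(tree$segments$main$profile) - 1)
  ffr_pre <- compute_ffr(sol_pre, "main", site_s)
  ffr_invasive_pre <- simulate_invasive(min(1, ffr_pre), config$sigma_pre)

  plans_b <- plan_blinded(tree, ffr_profile(sol_pre), les, catalog)
  if (length(plans_b) == 0L)
    stop_ffrct("no stent target", class = "ffrct_config_error")
  tree_b <- apply_stent(tree, plans_b)
  outlets_b <- assign_outlets(tree_b, inflow, props,
                              hyperemia_factor = config$hyperemia_factor)
  ffr_post_b <- compute_ffr(solve_steady(tree_b, outlets_b, inflow$qbar_ml_s,
                                         props), "main", site_s)

  plans_nb <- emulate_clinician_plan(plans_b, tree, config, catalog)
  tree_nb <- apply_stent(tree, plans_nb)
  outlets_nb <- assign_outlets(tree_nb, inflow, props,
                               hyperemia_factor = config$hyperemia_factor)
  ffr_post_nb <- compute_ffr(solve_steady(tree_nb, outlets_nb,
                                          inflow$qbar_ml_s, props),
                             "main", site_s)
  ffr_invasive_post <- simulate_invasive(min(1, ffr_post_nb),
                                         config$sigma_post)
  row <- data.frame(
    id = NA_character_, label = vs$label,
    vm_ml = tree$myocardial_volume_ml,
    pct_ds = max(les$pct_ds), lesion_length = sum(les$s_end - les$s_start),
    n_stents_blinded = length(plans_b),
    blinded_length = sum(vapply(plans_b, function(p) p$length, 0)),
    nonblinded_length = sum(vapply(plans_nb, function(p) p$length, 0)),
    ffr_ct_pre = ffr_pre, ffr_invasive_pre = ffr_invasive_pre,
    ffr_ct_post_blinded = ffr_post_b,
    ffr_ct_post_nonblinded = ffr_post_nb,
    ffr_invasive_post = ffr_invasive_post)
  list(row = row, plans = list(blinded = plans_b, non_blinded = plans_nb))
}

#' @export
print.ffr_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("<ffr_cohort> %d vessels (%d discovery / %d validation), %d attempts\n",
              nrow(r), sum(r$cohort == "discovery"),
              sum(r$cohort == "validation"), x$attempts))
  cat(sprintf("  median invasive pre-PCI FFR %.2f, post-PCI %.2f\n",
              stats::median(r$ffr_invasive_pre),
              stats::median(r$ffr_invasive_post)))
  invisible(x)
}

#' Write the cohort record table as CSV
#'
#' @param cohort an `ffr_cohort`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cohort$records
  # serialize doubles at full precision so re-analysis of the CSV
  # reproduces the report bit for bit
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort record table back from CSV
#'
#' @param path CSV path written by [write_cohort_csv()]
#' @return data frame of vessel records
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
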