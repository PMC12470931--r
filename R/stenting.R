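# Virtual stenting: blinded (algorithmic) and non-blinded (externally
# specified) stent plans, applied as lumen modifications. A stent sets the
# lumen to a linear taper between its end diameters (never below the native
# lumen), with smoothstep blend zones at each end so the stented and native
# segments join continuously.

#' Catalog of available stent sizes
#'
#' Defaults mirror contemporary drug-eluting stent offerings: diameters
#' 2.25-5.0 mm in 0.25 mm steps and lengths 8-38 mm. The 2.25 mm floor
#' matches the usual minimum treatable vessel diameter.
#'
#' @param diameters_mm ascending positive diameters (mm)
#' @param lengths_mm ascending positive lengths (mm)
#' @return object of class `stent_catalog`
#' @export
stent_catalog <- function(diameters_mm = seq(2.25, 5, by = 0.25),
                          lengths_mm = c(8, 12, 15, 18, 23, 28, 33, 38)) {
  stopifnot(all(diameters_mm > 0), all(lengths_mm > 0),
            !is.unsorted(diameters_mm), !is.unsorted(lengths_mm))
  structure(list(diameters_mm = diameters_mm, lengths_mm = lengths_mm),
            class = "stent_catalog")
}

#' A stent plan
#'
#' @param segment_id segment carrying the stent
#' @param center_s stent center, arc length on the segment (mm)
#' @param length stent length (mm)
#' @param d_prox,d_dist target lumen diameter at the proximal/distal stent
#'   end (mm)
#' @param mode `"blinded"` or `"non_blinded"`
#' @return object of class `stent_plan`
#' @export
stent_plan <- function(segment_id, center_s, length, d_prox, d_dist,
                       mode = c("blinded", "non_blinded")) {
  mode <- match.arg(mode)
  if (length <= 0 || d_prox <= 0 || d_dist <= 0)
    stop_ffrct("stent length and diameters must be positive",
               class = "ffrct_stent_error")
  structure(list(segment_id = segment_id, center_s = center_s,
                 length = length, d_prox = d_prox, d_dist = d_dist,
                 mode = mode),
            class = "stent_plan")
}

#' @export
print.stent_plan <- function(x, ...) {
  cat(sprintf("<stent_plan %s> seg '%s', center %.1f mm, L %.0f mm, d %.2f->%.2f mm\n",
              x$mode, x$segment_id, x$center_s, x$length, x$d_prox, x$d_dist))
  invisible(x)
}

# nearest catalog diameter to target, ties toward the smaller size,
# never exceeding cap
nearest_catalog_diameter <- function(catalog, target, cap = Inf) {
  ds <- catalog$diameters_mm
  pick <- ds[order(abs(ds - target), ds)][1]
  if (pick > cap + 1e-9) {
    under <- ds[ds <= cap + 1e-9]
    pick <- if (length(under)) max(under) else min(ds)
  }
  pick
}

#' Plan stents algorithmically (blinded mode)
#'
#' The target region for each lesion is the union of the lesion extent and
#' the contiguous region around it where the per-mm FFR drop exceeds
#' `gradient_threshold`. Stent length is the smallest catalog length
#' covering the target plus `margin` on each side, centered on the target;
#' when even the longest catalog stent cannot cover it, multiple stents of
#' equal length are planned with pairwise overlap of at least 1 mm. End
#' diameters are the catalog sizes nearest the proximal/distal reference
#' diameters, never exceeding the proximal reference. A vessel with no
#' lesion and a flat FFR profile yields an empty plan.
#'
#' @param tree a [coronary_tree()]
#' @param ffr_profile data frame from [ffr_profile()] on the same geometry
#' @param lesions a `lesion_table` from [detect_lesions()]
#' @param catalog a [stent_catalog()]
#' @param margin extra coverage beyond the target on each side (mm)
#' @param gradient_threshold per-mm FFR drop flagging a hemodynamic
#'   hotspot (default 0.005/mm)
#' @param blend_length blend-zone length assumed when checking fit (mm)
#' @param min_overlap minimum pairwise overlap of adjacent stents (mm)
#' @return list of [stent_plan()]s (possibly empty)
#' @export
plan_blinded <- function(tree, ffr_profile, lesions, catalog = stent_catalog(),
                         margin = 2, gradient_threshold = 0.005,
                         blend_length = 1, min_overlap = 1) {
  plans <- list()
  if (nrow(lesions) == 0L) return(plans)
  for (i in seq_len(nrow(lesions))) {
    les <- lesions[i, ]
    seg <- les$segment_id
    prof <- tree$segments[[seg]]$profile
    s_lo <- prof$s_mm[1]
    s_hi <- prof$s_mm[length(prof$s_mm)]
    target <- c(les$s_start, les$s_end)
    # extend by the FFR-gradient hotspot contiguous with the lesion
    fp <- ffr_profile[ffr_profile$segment == seg, ]
    if (nrow(fp) > 2) {
      fp <- fp[order(fp$s_mm), ]
      fp <- fp[!duplicated(fp$s_mm), ]
      grad <- -diff(fp$ffr) / diff(fp$s_mm)
      hot <- c(grad > gradient_threshold, FALSE)
      for (w in run_windows(fp$s_mm, hot)) {
        if (w[1] <= target[2] + 1e-9 && w[2] >= target[1] - 1e-9)
          target <- c(min(target[1], w[1]), max(target[2], w[2]))
      }
    }
    span <- c(target[1] - margin, target[2] + margin)
    need <- span[2] - span[1]
    lmax <- max(catalog$lengths_mm)
    d_prox <- nearest_catalog_diameter(catalog, les$d_ref_prox,
                                       cap = les$d_ref_prox)
    d_dist <- nearest_catalog_diameter(catalog, les$d_ref_dist,
                                       cap = les$d_ref_prox)
    if (need <= lmax) {
      len <- min(catalog$lengths_mm[catalog$lengths_mm >= need])
      centers <- mean(span)
      lens <- len
    } else {
      k <- 2L
      while (k * lmax - (k - 1) * min_overlap < need) k <- k + 1L
      ok <- catalog$lengths_mm[k * catalog$lengths_mm -
                                 (k - 1) * min_overlap >= need]
      len <- min(ok)
      overlap <- (k * len - need) / (k - 1)
      starts <- span[1] + (seq_len(k) - 1) * (len - overlap)
      centers <- starts + len / 2
      lens <- rep(len, k)
    }
    for (j in seq_along(centers)) {
      lo <- centers[j] - lens[j] / 2 - blend_length
      hi <- centers[j] + lens[j] / 2 + blend_length
      if (lo < s_lo || hi > s_hi)
        stop_ffrct(paste0("planned stent (%.1f-%.1f mm) plus blend leaves segment ",
                          "'%s' [%.1f, %.1f]; target touches a tree inlet/outlet"),
                   lo, hi, seg, s_lo, s_hi, class = "ffrct_stent_error")
      plans[[length(plans) + 1L]] <-
        stent_plan(seg, centers[j], lens[j], d_prox, d_dist, mode = "blinded")
    }
  }
  plans
}

#' Echo an actual clinical stent as a plan (non-blinded mode)
#'
#' @param tree a [coronary_tree()]
#' @param segment_id segment carrying the stent
#' @param length stent length (mm), > 0
#' @param diameter stent diameter (mm); used for both ends unless
#'   `d_dist` is given
#' @param center_s stent center on the segment (mm)
#' @param d_dist optional distal diameter (mm)
#' @param blend_length blend length assumed when checking fit (mm)
#' @return a [stent_plan()] with mode `"non_blinded"`
#' @export
plan_non_blinded <- function(tree, segment_id, length, diameter, center_s,
                             d_dist = NULL, blend_length = 1) {
  if (length <= 0 || diameter <= 0)
    stop_ffrct("stent length and diameter must be positive",
               class = "ffrct_stent_error")
  prof <- tree$segments[[segment_id]]$profile
  lo <- center_s - length / 2 - blend_length
  hi <- center_s + length / 2 + blend_length
  if (lo < prof$s_mm[1] || hi > prof$s_mm[base::length(prof$s_mm)])
    stop_ffrct("stent (%.1f-%.1f mm) extends past segment '%s' ends",
               lo, hi, segment_id, class = "ffrct_stent_error")
  stent_plan(segment_id, center_s, length, diameter, d_dist %||% diameter,
             mode = "non_blinded")
}

# smoothstep on [0,1]
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# lumen diameter contributed by one plan at arc lengths s on its segment,
# given the *base* native diameters there; -Inf where the plan has no say
plan_shape <- function(plan, s, d_native, blend_length) {
  a <- plan$center_s - plan$length / 2
  b <- plan$center_s + plan$length / 2
  taper <- plan$d_prox + (plan$d_dist - plan$d_prox) *
    pmin(1, pmax(0, (s - a) / (b - a)))
  shape <- rep(-Inf, length(s))
  inside <- s >= a & s <= b
  shape[inside] <- taper[inside]
  # end values actually realized in-stent (max with native); the blend
  # carries the protrusion above the native lumen at the joint outward as a
  # smoothstep-decaying offset, so it vanishes identically when the stent
  # does not protrude and joins C1 at both ends
  na_a <- stats::approx(s, d_native, xout = a, rule = 2)$y
  na_b <- stats::approx(s, d_native, xout = b, rule = 2)$y
  off_a <- max(0, plan$d_prox - na_a)
  off_b <- max(0, plan$d_dist - na_b)
  prox <- s >= a - blend_length & s < a
  if (any(prox)) {
    u <- (a - s[prox]) / blend_length
    shape[prox] <- d_native[prox] + off_a * (1 - smoothstep(u))
  }
  dist <- s > b & s <= b + blend_length
  if (any(dist)) {
    u <- (s[dist] - b) / blend_length
    shape[dist] <- d_native[dist] + off_b * (1 - smoothstep(u))
  }
  shape
}

#' Apply stent plans to a tree
#'
#' Within the stent, the lumen diameter becomes the larger of the native
#' diameter and the linear taper between the plan's end diameters; over
#' `blend_length` beyond each end a smoothstep blends the stented diameter
#' back into the native lumen. The lumen is never reduced anywhere, and
#' geometry outside the stent and blend zones is untouched. Applying the
#' same plan twice is identical to applying it once: a stented tree
#' remembers its base geometry and plan set and is rebuilt from the base.
#'
#' @param tree a [coronary_tree()] or a previously stented tree
#' @param plans a [stent_plan()] or list of them
#' @param blend_length blend-zone length (mm), default 1
#' @return a `stented_tree` (also a valid [coronary_tree()])
#' @export
apply_stent <- function(tree, plans, blend_length = 1) {
  if (inherits(plans, "stent_plan")) plans <- list(plans)
  if (inherits(tree, "stented_tree")) {
    base <- attr(tree, "base_tree")
    old <- attr(tree, "plans")
    keys <- vapply(old, plan_key, "")
    for (p in plans)
      if (!plan_key(p) %in% keys) old[[length(old) + 1L]] <- p
    plans <- old
    tree <- base
  }
  base <- tree
  segs <- tree$segments
  for (p in plans) {
    if (is.null(segs[[p$segment_id]]))
      stop_ffrct("plan names unknown segment '%s'", p$segment_id,
                 class = "ffrct_stent_error")
    prof <- segs[[p$segment_id]]$profile
    lo <- p$center_s - p$length / 2 - blend_length
    hi <- p$center_s + p$length / 2 + blend_length
    if (lo < prof$s_mm[1] || hi > prof$s_mm[length(prof$s_mm)])
      stop_ffrct("stent blend zone (%.1f-%.1f mm) leaves segment '%s'",
                 lo, hi, p$segment_id, class = "ffrct_stent_error")
  }
  # densify each touched segment so stent/blend boundaries are resolved
  touched <- unique(vapply(plans, function(p) p$segment_id, ""))
  for (id in touched) {
    prof <- resample_profile(base$segments[[id]]$profile, 0.25)
    d0 <- 2 * prof$r_mm
    d <- d0
    for (p in plans) {
      if (p$segment_id != id) next
      shp <- plan_shape(p, prof$s_mm, d0, blend_length)
      d <- pmax(d, shp)
    }
    segs[[id]]$profile <- centerline_profile(prof$s_mm, d / 2)
  }
  out <- coronary_tree(segs, base$inlet, base$myocardial_volume_ml)
  class(out) <- c("stented_tree", class(out))
  attr(out, "base_tree") <- base
  attr(out, "plans") <- plans
  attr(out, "blend_length") <- blend_length
  out
}

plan_key <- function(p) {
  sprintf("%s|%.9f|%.9f|%.9f|%.9f|%s", p$segment_id, p$center_s, p$length,
          p$d_prox, p$d_dist, p$mode)
}

#' Serialize stent plans to CSV
#'
#' @param plans list of [stent_plan()]s
#' @param path output path
#' @return the data frame written, invisibly
#' @export
write_plans_csv <- function(plans, path) {
  if (inherits(plans, "stent_plan")) plans <- list(plans)
  df <- do.call(rbind, lapply(plans, function(p)
    data.frame(segment = p$segment_id, center_s_mm = p$center_s,
               length_mm = p$length, d_prox_mm = p$d_prox,
               d_dist_mm = p$d_dist, mode = p$mode)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
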