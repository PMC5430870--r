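#' Overlap report between a simulated and a reference mask
#'
#' Computes the Jaccard score `JS = |S ∩ GT| / |S ∪ GT|` and the Dice
#' coefficient `DC = 2 |S ∩ GT| / (|S| + |GT|)` from integer voxel counts,
#' so the identity `DC = 2 JS / (1 + JS)` holds to machine precision.  Two
#' empty masks make both metrics undefined and raise an error.
#'
#' @param s Simulated binary mask (logical array).
#' @param gt Ground-truth binary mask, same shape.
#' @return Object of class `overlap_report` with `js`, `dc` and the counts
#'   `n_s`, `n_gt`, `n_intersection`, `n_union`.
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); b <- a
#' a[1:2, , ] <- TRUE; b[2:3, , ] <- TRUE
#' overlap_report(a, b)
#' @export
overlap_report <- function(s, gt) {
  if (!identical(dim(s), dim(gt))) stop("mask shapes differ", call. = FALSE)
  s <- as.logical(s); gt <- as.logical(gt)
  n_s <- sum(s); n_gt <- sum(gt)
  if (n_s == 0 && n_gt == 0) {
    stop("both masks are empty: overlap metrics are undefined", call. = FALSE)
  }
  n_i <- sum(s & gt)
  n_u <- n_s + n_gt - n_i
  structure(list(js = n_i / n_u, dc = 2 * n_i / (n_s + n_gt),
                 n_s = n_s, n_gt = n_gt,
                 n_intersection = n_i, n_union = n_u),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> JS = %.4f, DC = %.4f (|S| = %d, |GT| = %d, |S∩GT| = %d)\n",
              x$js, x$dc, x$n_s, x$n_gt, x$n_intersection))
  invisible(x)
}

#' Jaccard score
#'
#' Intersection over union of two binary masks.
#'
#' @inheritParams overlap_report
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(s, gt) overlap_report(s, gt)$js

#' Dice coefficient
#'
#' Twice the intersection over the size sum of two binary masks.
#'
#' @inheritParams overlap_report
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(s, gt) overlap_report(s, gt)$dc

#' Define an ablation scenario
#'
#' Bundles everything one growth experiment needs: anatomy, DTI, initial
#' tumor, therapy plans, configuration and horizon.  The full model run on
#' this scenario serves as the ablation ground truth.
#'
#' @param vol [labeled_volume()].
#' @param dti DTI-like [tensor_field()] (raw, unitless).
#' @param init Initial [density_field()].
#' @param rt_plan,chemo_plan Therapy plans (either may be `NULL`).
#' @param config Configuration list ([default_config()]).
#' @param days Simulation horizon, days.
#' @return Object of class `growth_scenario`.
#' @export
growth_scenario <- function(vol, dti, init, rt_plan = NULL, chemo_plan = NULL,
                            config = default_config(), days = config$t_end) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(dti, "tensor_field"),
            inherits(init, "density_field"))
  structure(list(vol = vol, dti = dti, init = init, rt_plan = rt_plan,
                 chemo_plan = chemo_plan, config = config, days = days),
            class = "growth_scenario")
}

# Run one scenario variant and return the detection mask.
run_variant <- function(scenario, variant) {
  cfg <- finalize_config(unclass(scenario$config))
  rt <- scenario$rt_plan
  ch <- scenario$chemo_plan
  params <- tissue_params(cfg$d_gm, cfg$d_wm, cfg$rho)
  use_dti <- TRUE
  switch(variant,
    full = NULL,
    no_chemo = { ch <- NULL },
    no_rt = { rt <- NULL },
    no_treatment = { rt <- NULL; ch <- NULL },
    no_dti = { use_dti <- FALSE },
    no_viscoelastic = { cfg$use_viscoelastic <- FALSE },
    stop(sprintf("unknown ablation variant '%s'", variant), call. = FALSE)
  )
  diffusion <- if (use_dti) {
    build_growth_tensor(scenario$dti, scenario$vol, params,
                        normalization = cfg$e1_normalization)
  } else {
    scalar_diffusion_map(scenario$vol, params)
  }
  res <- simulate_growth(scenario$init, scenario$vol, diffusion,
                         rt_plan = rt, chemo_plan = ch, config = cfg,
                         days = scenario$days,
                         save_every = scenario$days)
  extract_mask(res, cfg$u_detect)
}

#' Run a model-component ablation study
#'
#' Simulates the full model on a scenario to obtain the reference
#' detection mask, then re-runs each reduced variant (dropping
#' chemotherapy, radiotherapy, both, the DTI tensor, or the viscoelastic
#' pathway) and scores it against the full model with Jaccard and Dice.
#' Because the reference is the full model itself (not an external ground
#' truth), the reported decreases measure each component's influence on
#' the predicted tumor extent.
#'
#' @param scenario A [growth_scenario()].
#' @param variants Character vector of variants to run; any of
#'   `"no_chemo"`, `"no_rt"`, `"no_treatment"`, `"no_dti"`,
#'   `"no_viscoelastic"`.
#' @return data.frame with columns `variant`, `js`, `dc`, `d_js_pct`,
#'   `d_dc_pct` (percentage-point decreases from the full model's perfect
#'   self-overlap), including a leading `full` row.
#' @export
run_ablation <- function(scenario,
                         variants = c("no_chemo", "no_rt", "no_treatment",
                                      "no_dti", "no_viscoelastic")) {
  stopifnot(inherits(scenario, "growth_scenario"))
  gt <- run_variant(scenario, "full")
  rows <- lapply(c("full", variants), function(v) {
    m <- if (v == "full") gt else run_variant(scenario, v)
    rep <- overlap_report(m, gt)
    data.frame(variant = v, js = rep$js, dc = rep$dc,
               d_js_pct = 100 * (1 - rep$js), d_dc_pct = 100 * (1 - rep$dc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
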