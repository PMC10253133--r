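# Core scenarios: the per-core ground-truth recipes the simulator renders.
#
# A scenario fixes tissue composition, marker-positive fractions, staining
# intensities and nucleus morphology for one TMA core. Presets encode both
# unambiguous cores and the five ambiguity patterns a screening pipeline must
# flag: scant tissue, atypical tumour morphology, heavy immune infiltrate,
# normal-only mucosa, and weak/patchy immunostaining.

# Per-class morphology defaults (um). Tumour nuclei are large and eccentric,
# immune nuclei small and round, stromal nuclei spindle-shaped.
CLASS_RADIUS_MEAN <- c(NormalEpithelium = 3.2, Tumour = 5.2,
                       ImmuneInfiltrate = 2.2, Stroma = 2.6)
CLASS_RADIUS_SD   <- CLASS_RADIUS_MEAN * 0.10
CLASS_ASPECT      <- c(NormalEpithelium = 1.15, Tumour = 1.7,
                       ImmuneInfiltrate = 1.0, Stroma = 3.0)
CLASS_HEMA_OD     <- c(NormalEpithelium = 0.55, Tumour = 0.60,
                       ImmuneInfiltrate = 0.80, Stroma = 0.70)
CLASS_DAB_OD      <- c(NormalEpithelium = 0.65, Tumour = 0.65,
                       ImmuneInfiltrate = 0.55, Stroma = 0.55)

named4 <- function(x, name) {
  if (length(x) == 1L) x <- rep(x, 4L)
  if (is.null(names(x))) names(x) <- TISSUE_CLASSES
  if (!setequal(names(x), TISSUE_CLASSES))
    stop(sprintf("'%s' must be named with the four tissue classes", name),
         call. = FALSE)
  x[TISSUE_CLASSES]
}

#' Define a simulated TMA core scenario
#'
#' @param composition named fractions per tissue class summing to 1 (cell
#'   fractions; classes are laid out as contiguous angular sectors so that
#'   neighbourhood features see realistic locally-pure tissue).
#' @param marker_positive_fraction per-class probability that a nucleus is
#'   marker-positive (stained with DAB).
#' @param dab_od,hema_od per-class mean nucleus OD for DAB (positive nuclei
#'   only) and haematoxylin.
#' @param density nuclei per mm^2 of tissue.
#' @param radius_mean,radius_sd per-class nucleus equivalent radius (um).
#' @param aspect per-class ellipse aspect ratio (major/minor).
#' @param tissue_fill fraction of the nominal core disc occupied by tissue
#'   (scant-tissue scenario; 1 = full disc).
#' @param patchiness amplitude of the low-frequency sinusoidal modulation of
#'   DAB OD (0 = uniform staining; the weak/patchy scenario).
#' @param blank if `TRUE` the core is empty (orientation blank); implies zero
#'   nuclei.
#' @param id short scenario identifier carried into the ground truth.
#' @return An object of class `core_scenario`.
#' @export
core_scenario <- function(composition = c(NormalEpithelium = 1, Tumour = 0,
                                          ImmuneInfiltrate = 0, Stroma = 0),
                          marker_positive_fraction = 0.9,
                          dab_od = CLASS_DAB_OD,
                          hema_od = CLASS_HEMA_OD,
                          density = 2000,
                          radius_mean = CLASS_RADIUS_MEAN,
                          radius_sd = CLASS_RADIUS_SD,
                          aspect = CLASS_ASPECT,
                          tissue_fill = 1,
                          patchiness = 0,
                          blank = FALSE,
                          id = "custom") {
  composition <- named4(composition, "composition")
  if (any(composition < 0) || any(composition > 1))
    stop("composition fractions must lie in [0, 1]", call. = FALSE)
  if (!blank && abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1", call. = FALSE)
  marker_positive_fraction <- named4(marker_positive_fraction,
                                     "marker_positive_fraction")
  if (any(marker_positive_fraction < 0) || any(marker_positive_fraction > 1))
    stop("marker_positive_fraction must lie in [0, 1]", call. = FALSE)
  if (tissue_fill < 0 || tissue_fill > 1)
    stop("tissue_fill must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(density, "density")
  if (blank) density <- 0
  structure(list(composition = composition,
                 marker_positive_fraction = marker_positive_fraction,
                 dab_od = named4(dab_od, "dab_od"),
                 hema_od = named4(hema_od, "hema_od"),
                 density = density,
                 radius_mean = named4(radius_mean, "radius_mean"),
                 radius_sd = named4(radius_sd, "radius_sd"),
                 aspect = named4(aspect, "aspect"),
                 tissue_fill = if (blank) 0 else tissue_fill,
                 patchiness = patchiness,
                 blank = isTRUE(blank),
                 id = id),
            class = "core_scenario")
}

#' @export
print.core_scenario <- function(x, ...) {
  cat(sprintf("Core scenario '%s'%s\n", x$id, if (x$blank) " (blank)" else ""))
  if (!x$blank) {
    cat("  composition:",
        paste(sprintf("%s %.2f", names(x$composition), x$composition),
              collapse = ", "), "\n")
    cat(sprintf("  density %g /mm^2, tissue fill %.2f, patchiness %.2f\n",
                x$density, x$tissue_fill, x$patchiness))
  }
  invisible(x)
}

# ---- Presets ---------------------------------------------------------------

#' Scenario presets
#'
#' Ready-made [core_scenario()]s: unambiguous cores (normal mucosa,
#' marker-proficient tumour, marker-deficient tumour) and the five ambiguity
#' patterns that should be flagged for manual review, plus orientation blanks
#' and sub-threshold scant cores that the dearrayer should mark invalid.
#'
#' @name scenario_presets
#' @return A [core_scenario()].
NULL

#' @rdname scenario_presets
#' @export
scenario_normal_proficient <- function() core_scenario(
  composition = c(NormalEpithelium = 0.88, Tumour = 0, ImmuneInfiltrate = 0.02,
                  Stroma = 0.10),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.93,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  id = "normal_proficient")

#' @rdname scenario_presets
#' @export
scenario_tumour_proficient <- function() core_scenario(
  composition = c(NormalEpithelium = 0, Tumour = 0.87, ImmuneInfiltrate = 0.03,
                  Stroma = 0.10),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.92,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  id = "tumour_proficient")

#' @rdname scenario_presets
#' @export
scenario_tumour_deficient <- function() core_scenario(
  composition = c(NormalEpithelium = 0, Tumour = 0.87, ImmuneInfiltrate = 0.03,
                  Stroma = 0.10),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.04,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  id = "tumour_deficient")

#' @rdname scenario_presets
#' @export
scenario_blank <- function() core_scenario(blank = TRUE, id = "blank")

#' @rdname scenario_presets
#' @export
scenario_excluded_scant <- function() core_scenario(
  composition = c(NormalEpithelium = 0.5, Tumour = 0, ImmuneInfiltrate = 0,
                  Stroma = 0.5),
  tissue_fill = 0.03, id = "excluded_scant")

#' @rdname scenario_presets
#' @export
scenario_scant_mixed <- function() core_scenario(
  composition = c(NormalEpithelium = 0.42, Tumour = 0.42,
                  ImmuneInfiltrate = 0.04, Stroma = 0.12),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.9,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  tissue_fill = 0.25, id = "ambiguous_scant_tissue")

#' @rdname scenario_presets
#' @export
scenario_atypical_tumour <- function() core_scenario(
  composition = c(NormalEpithelium = 0.12, Tumour = 0.58,
                  ImmuneInfiltrate = 0.05, Stroma = 0.25),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.9,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  radius_mean = c(NormalEpithelium = 3.2, Tumour = 3.8, ImmuneInfiltrate = 2.2,
                  Stroma = 2.6),
  aspect = c(NormalEpithelium = 1.15, Tumour = 1.25, ImmuneInfiltrate = 1.0,
             Stroma = 3.0),
  id = "ambiguous_atypical_tumour")

#' @rdname scenario_presets
#' @export
scenario_immune_rich <- function() core_scenario(
  composition = c(NormalEpithelium = 0, Tumour = 0.40, ImmuneInfiltrate = 0.45,
                  Stroma = 0.15),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.9,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  id = "ambiguous_immune_rich")

#' @rdname scenario_presets
#' @export
scenario_normal_mucosa <- function() core_scenario(
  composition = c(NormalEpithelium = 0.62, Tumour = 0, ImmuneInfiltrate = 0.03,
                  Stroma = 0.35),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.93,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  id = "ambiguous_normal_mucosa")

#' @rdname scenario_presets
#' @export
scenario_patchy_stain <- function() core_scenario(
  composition = c(NormalEpithelium = 0, Tumour = 0.85, ImmuneInfiltrate = 0.03,
                  Stroma = 0.12),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.55,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  patchiness = 0.5, id = "ambiguous_patchy_stain")

#' @rdname scenario_presets
#' @export
scenario_immune_patchy <- function() core_scenario(
  composition = c(NormalEpithelium = 0, Tumour = 0.50, ImmuneInfiltrate = 0.35,
                  Stroma = 0.15),
  marker_positive_fraction = c(NormalEpithelium = 0.93, Tumour = 0.55,
                               ImmuneInfiltrate = 0.3, Stroma = 0.1),
  patchiness = 0.5, id = "ambiguous_immune_patchy")

#' Expected certification call implied by a scenario
#'
#' Applies the certification rules to the scenario's intended cell fractions
#' (no detection or classification error), giving the call a perfect pipeline
#' would make. Scenarios whose fractions fall between the thresholds map to
#' `Flagged`; blanks and sub-threshold scant cores map to `Invalid`.
#'
#' @param scenario a [core_scenario()].
#' @param params a [certification_params()].
#' @param min_valid_fill tissue fill below which the dearrayer is expected to
#'   invalidate the core.
#' @return Character: expected `call` value (see [certify()]).
#' @export
scenario_expected_call <- function(scenario, params = certification_params(),
                                   min_valid_fill = 0.125) {
  if (scenario$blank || scenario$tissue_fill < min_valid_fill) return("Invalid")
  comp <- scenario$composition
  pos <- scenario$marker_positive_fraction
  denom <- if (params$histology_denominator == "all_cells") sum(comp)
           else sum(comp[EPITHELIAL_CLASSES])
  epi <- sum(comp[EPITHELIAL_CLASSES])
  marker_frac <- if (epi > 0)
    sum(comp[EPITHELIAL_CLASSES] * pos[EPITHELIAL_CLASSES]) / epi else NA_real_
  hist_call <- if (comp[["NormalEpithelium"]] / denom >= params$threshold) "Normal"
    else if (comp[["Tumour"]] / denom >= params$threshold) "Tumour" else NA
  marker_call <- if (is.na(marker_frac)) NA
    else if (marker_frac >= params$threshold) "Proficient"
    else if (1 - marker_frac >= params$threshold) "Deficient" else NA
  if (is.na(hist_call) || is.na(marker_call)) "Flagged"
  else paste0("MLH1", marker_call, hist_call)
}
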