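# Per-core certification: aggregate composite cell classes per core and
# certify histology (normal vs tumour) and marker status (proficient vs
# deficient) at a supermajority threshold, flagging ambiguous cores for
# manual review. Histology and marker status are assessed separately to
# prevent confounding; marker fractions use epithelial (normal + tumour)
# cells only, disregarding stroma and immune infiltrate.

CORE_CALLS <- c("MLH1ProficientNormal", "MLH1DeficientNormal",
                "MLH1ProficientTumour", "MLH1DeficientTumour",
                "Flagged", "Invalid")

#' Certification parameters
#'
#' @param threshold supermajority fraction required to certify a histology or
#'   marker call (default 0.75, i.e. >= 75 percent, compared inclusively).
#'   Must exceed 0.5 so that at most one class can certify.
#' @param histology_denominator `"all_cells"` (default: histology fractions
#'   are taken over every classified cell) or `"epithelial_cells"`.
#' @param min_cells cores with fewer classified cells are Invalid.
#' @return Object of class `certification_params`.
#' @export
certification_params <- function(threshold = 0.75,
                                 histology_denominator = c("all_cells",
                                                           "epithelial_cells"),
                                 min_cells = 20L) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  if (min_cells < 1) stop("min_cells must be >= 1", call. = FALSE)
  structure(list(threshold = threshold,
                 histology_denominator = match.arg(histology_denominator),
                 min_cells = as.integer(min_cells)),
            class = "certification_params")
}

#' Summarise the cells of one core
#'
#' Exact composite-class counts: per-tissue-class totals plus marker-positive
#' and marker-negative counts among epithelial (normal + tumour) cells.
#' Unscored or unclassified cells are excluded.
#'
#' @param cells classified cells of a single core (`tissue_class`,
#'   `base_class` columns).
#' @param core_label label attached to the summary.
#' @return Object of class `core_summary` (a one-row list of counts).
#' @export
summarize_core <- function(cells, core_label = NA_character_) {
  ok <- !is.na(cells$tissue_class) & !is.na(cells$base_class)
  cells <- cells[ok, , drop = FALSE]
  cnt <- function(cls) sum(cells$tissue_class == cls)
  epi <- cells$tissue_class %in% EPITHELIAL_CLASSES
  structure(list(core_label = core_label,
                 n_normal = cnt("NormalEpithelium"),
                 n_tumour = cnt("Tumour"),
                 n_immune = cnt("ImmuneInfiltrate"),
                 n_stroma = cnt("Stroma"),
                 n_epi_pos = sum(epi & cells$base_class == "Positive"),
                 n_epi_neg = sum(epi & cells$base_class == "Negative"),
                 n_total = nrow(cells)),
            class = "core_summary")
}

#' Certify one core
#'
#' The decision tree: cores with fewer than `min_cells` classified cells are
#' `Invalid`. Otherwise histology is certified `Normal` or `Tumour` when the
#' corresponding fraction reaches the threshold, and marker status
#' `Proficient`/`Deficient` when the positive (resp. negative) fraction of
#' epithelial cells reaches it. Both certain gives the combined call; any
#' uncertainty flags the core with the failing component(s) as the reason.
#' A core without epithelial cells has an undefined marker fraction and is
#' flagged for both. A deficient-normal call is biologically unexpected and
#' triggers a warning.
#'
#' @param summary a [summarize_core()] result.
#' @param params a [certification_params()].
#' @return One-row data.frame: `core_label`, `call`, `flag_reason` (`none`,
#'   `Histology`, `MLH1`, `Both`), `histology_fraction`, `marker_fraction`
#'   (positive fraction; `NA` when undefined).
#' @export
certify <- function(summary, params = certification_params()) {
  s <- summary
  row <- function(call, reason, hf, mf)
    data.frame(core_label = s$core_label, call = call, flag_reason = reason,
               histology_fraction = hf, marker_fraction = mf,
               n_total = s$n_total, stringsAsFactors = FALSE)
  if (s$n_total < params$min_cells)
    return(row("Invalid", "none", NA_real_, NA_real_))
  denom <- if (params$histology_denominator == "all_cells") s$n_total
           else s$n_normal + s$n_tumour
  f_normal <- if (denom > 0) s$n_normal / denom else 0
  f_tumour <- if (denom > 0) s$n_tumour / denom else 0
  hist_call <- if (f_normal >= params$threshold) "Normal"
    else if (f_tumour >= params$threshold) "Tumour" else NA_character_
  hist_frac <- max(f_normal, f_tumour)
  n_epi <- s$n_epi_pos + s$n_epi_neg
  if (n_epi > 0) {
    f_pos <- s$n_epi_pos / n_epi
    marker_call <- if (f_pos >= params$threshold) "Proficient"
      else if (1 - f_pos >= params$threshold) "Deficient" else NA_character_
  } else { f_pos <- NA_real_; marker_call <- NA_character_ }
  if (!is.na(hist_call) && !is.na(marker_call)) {
    call <- paste0("MLH1", marker_call, hist_call)
    if (call == "MLH1DeficientNormal")
      warning(sprintf(paste0("core %s certified as deficient normal ",
                             "epithelium, which is biologically unexpected"),
                      s$core_label), call. = FALSE)
    return(row(call, "none", hist_frac, f_pos))
  }
  reason <- if (is.na(hist_call) && is.na(marker_call)) "Both"
    else if (is.na(hist_call)) "Histology" else "MLH1"
  row("Flagged", reason, hist_frac, f_pos)
}

#' Certify every valid core of a grid
#'
#' @param grid a `tma_grid` from [dearray()].
#' @param cells classified cell table with `core_label` set (e.g. by
#'   [assign_cells_to_cores()]).
#' @param params a [certification_params()].
#' @return Object of class `core_calls`: data.frame of per-core calls
#'   (invalid grid positions included with call `Invalid`), with a `tallies`
#'   attribute counting certified / flagged-by-reason / invalid cores.
#' @export
certify_all <- function(grid, cells, params = certification_params()) {
  stopifnot(inherits(grid, "tma_grid"))
  out <- vector("list", nrow(grid$cores))
  for (i in seq_len(nrow(grid$cores))) {
    lab <- grid$cores$label[i]
    if (!grid$cores$valid[i]) {
      out[[i]] <- data.frame(core_label = lab, call = "Invalid",
                             flag_reason = "none",
                             histology_fraction = NA_real_,
                             marker_fraction = NA_real_, n_total = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    cc <- cells[!is.na(cells$core_label) & cells$core_label == lab, ,
                drop = FALSE]
    out[[i]] <- certify(summarize_core(cc, lab), params)
  }
  calls <- do.call(rbind, out)
  tallies <- c(certified = sum(!calls$call %in% c("Flagged", "Invalid")),
               flagged_histology = sum(calls$call == "Flagged" &
                                         calls$flag_reason == "Histology"),
               flagged_mlh1 = sum(calls$call == "Flagged" &
                                    calls$flag_reason == "MLH1"),
               flagged_both = sum(calls$call == "Flagged" &
                                    calls$flag_reason == "Both"),
               invalid = sum(calls$call == "Invalid"))
  structure(calls, tallies = tallies, class = c("core_calls", "data.frame"))
}

#' @export
print.core_calls <- function(x, ...) {
  t <- attr(x, "tallies")
  cat(sprintf(paste0("Core calls: %d certified, %d flagged ",
                     "(histology %d, marker %d, both %d), %d invalid\n"),
              t[["certified"]],
              t[["flagged_histology"]] + t[["flagged_mlh1"]] + t[["flagged_both"]],
              t[["flagged_histology"]], t[["flagged_mlh1"]], t[["flagged_both"]],
              t[["invalid"]]))
  NextMethod()
}
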