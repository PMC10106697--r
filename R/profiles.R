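#' Default cell-type profiles for zebrafish spermatogenesis
#'
#' Builds the twelve-type \code{\linkS4class{ClassProfileSet}} used throughout
#' the package. Nuclear diameters and relative DAPI intensities of the four
#' spermatogonial classes are the published morphometric values for zebrafish
#' (diameter in micrometres, DAPI normalized to the \code{SPG-A(2,4,8-cell)}
#' reference class):
#' \itemize{
#'   \item SPG-A(1-cell): diameter 6.47 +/- 0.95, DAPI 0.67 +/- 0.16
#'   \item SPG-A(2,4,8-cell): 5.74 +/- 0.82, DAPI 1 +/- 0.24 (reference)
#'   \item SPG-B(16,32-cell): 5.01 +/- 0.53, DAPI 2.24 +/- 0.39
#'   \item SPG-B(64,128,256-cell): 4.14 +/- 0.40, DAPI 1.95 +/- 0.44
#' }
#' Meiotic and post-meiotic types follow the decreasing nuclear size and
#' increasing condensation along spermatogenesis (SPC-I 6.0, SPC-II 4.0,
#' SPD 3.0, SPZ 2.0 micrometres; DAPI 1.5, 2.0, 2.5, 3.0). Relative marker
#' levels encode the ordinal relations seen by immunofluorescence: Ddx4
#' decreases progressively and is absent from SPZ; Piwil1 is highest in type A
#' spermatogonia; Pcna is high in mitotically cycling spermatogonia, polar
#' then punctate then absent across meiotic prophase; Sycp3 is nuclear from
#' late type B spermatogonia (aggregated dots) and spreads polar to stripe to
#' whole-nucleus across SPC-I substages. The magnitudes of the marker levels
#' are editable calibration parameters, not published constants.
#'
#' @return a \code{\linkS4class{ClassProfileSet}} with 12 labels.
#' @examples
#' ps <- makeDefaultProfiles()
#' profileTable(ps)[, 1:5]
#' @export
makeDefaultProfiles <- function() {
  p <- data.frame(
    label = .CELL_LABELS,
    diameter_mean = c(6.47, 5.74, 5.01, 4.14, 6.0, 6.0, 6.0, 6.0, 6.0, 4.0, 3.0, 2.0),
    diameter_sd   = c(0.95, 0.82, 0.53, 0.40, 0.7, 0.7, 0.7, 0.7, 0.7, 0.4, 0.3, 0.2),
    dapi_rel_mean = c(0.67, 1.00, 2.24, 1.95, 1.5, 1.5, 1.5, 1.5, 1.5, 2.0, 2.5, 3.0),
    dapi_rel_sd   = c(0.16, 0.24, 0.39, 0.44, 0.20, 0.20, 0.20, 0.20, 0.20, 0.20, 0.25, 0.30),
    ddx4   = c(1.0, 1.0, 0.60, 0.60, 0.15, 0.15, 0.15, 0.15, 0.15, 0.08, 0.08, 0.00),
    piwil1 = c(1.3, 1.0, 0.50, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.00),
    sycp3  = c(0.0, 0.0, 0.00, 0.30, 1.00, 1.00, 1.00, 1.00, 1.00, 0.00, 0.00, 0.00),
    pcna   = c(0.1, 1.0, 1.00, 1.00, 1.00, 0.80, 0.50, 0.25, 0.00, 0.00, 0.00, 0.00),
    sycp3_pattern = c("absent", "absent", "absent", "dots",
                      "polar", "polar", "stripe", "stripe", "whole",
                      "absent", "absent", "absent"),
    pcna_pattern = c("low", "high", "high", "high",
                     "polar", "complementary", "punctate", "punctate", "absent",
                     "absent", "absent", "absent"),
    nucleolus_min = c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    nucleolus_max = c(0L, 1L, 3L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    ## nucleolus diameter as a fraction of the nuclear diameter: one large
    ## nucleolus in the reference class, smaller ones in SPG-B(16,32-cell)
    nucleolus_rel_diam = c(0, 0.25, 0.16, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    ## coverage target of the sycp3 stripe (only used by stripe patterns)
    sycp3_coverage = c(NA, NA, NA, NA, NA, NA, 0.575, 0.75, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  sizes <- list(
    "SPG-A(1-cell)" = 1L,
    "SPG-A(2,4,8-cell)" = c(2L, 4L, 8L),
    "SPG-B(16,32-cell)" = c(16L, 32L),
    "SPG-B(64,128,256-cell)" = c(64L, 128L, 256L),
    "SPC-I(L)" = c(8L, 16L, 32L, 64L),
    "SPC-I(EZ)" = c(8L, 16L, 32L, 64L),
    "SPC-I(MZ)" = c(8L, 16L, 32L, 64L),
    "SPC-I(LZ)" = c(8L, 16L, 32L, 64L),
    "SPC-I(P)" = c(8L, 16L, 32L, 64L),
    "SPC-II" = c(16L, 32L, 64L, 128L),
    "SPD" = 1:256,
    "SPZ" = 1:256
  )
  new("ClassProfileSet", profiles = p, cystSizes = sizes,
      reference = "SPG-A(2,4,8-cell)")
}

#' Read / write a profile set as YAML
#'
#' Profiles are serialized as a YAML map keyed by the cell-type labels, with
#' the reference label stored under \code{reference}.
#'
#' @param path file path.
#' @return \code{readProfiles}: a \code{\linkS4class{ClassProfileSet}};
#'   \code{writeProfiles}: \code{path}, invisibly.
#' @export
readProfiles <- function(path) {
  y <- yaml::read_yaml(path)
  ref <- y$reference
  y$reference <- NULL
  rows <- lapply(names(y), function(lab) {
    e <- y[[lab]]
    data.frame(label = lab,
               diameter_mean = e$diameter_mean, diameter_sd = e$diameter_sd,
               dapi_rel_mean = e$dapi_rel_mean, dapi_rel_sd = e$dapi_rel_sd,
               ddx4 = e$marker_rel$Ddx4, piwil1 = e$marker_rel$Piwil1,
               sycp3 = e$marker_rel$Sycp3, pcna = e$marker_rel$Pcna,
               sycp3_pattern = e$sycp3_pattern, pcna_pattern = e$pcna_pattern,
               nucleolus_min = as.integer(e$nucleolus_count_range[1]),
               nucleolus_max = as.integer(e$nucleolus_count_range[2]),
               nucleolus_rel_diam = e$nucleolus_rel_diam,
               sycp3_coverage = if (is.null(e$sycp3_coverage)) NA_real_ else e$sycp3_coverage,
               stringsAsFactors = FALSE)
  })
  sizes <- lapply(y, function(e) as.integer(e$cyst_sizes))
  new("ClassProfileSet", profiles = do.call(rbind, rows),
      cystSizes = sizes, reference = ref)
}

#' @rdname readProfiles
#' @param profiles a \code{\linkS4class{ClassProfileSet}}
#' @export
writeProfiles <- function(profiles, path) {
  p <- profileTable(profiles)
  out <- lapply(seq_len(nrow(p)), function(i) {
    r <- as.list(p[i, ])
    e <- list(
      diameter_mean = r$diameter_mean, diameter_sd = r$diameter_sd,
      dapi_rel_mean = r$dapi_rel_mean, dapi_rel_sd = r$dapi_rel_sd,
      marker_rel = list(Ddx4 = r$ddx4, Piwil1 = r$piwil1,
                        Sycp3 = r$sycp3, Pcna = r$pcna),
      sycp3_pattern = r$sycp3_pattern, pcna_pattern = r$pcna_pattern,
      nucleolus_count_range = c(r$nucleolus_min, r$nucleolus_max),
      nucleolus_rel_diam = r$nucleolus_rel_diam,
      cyst_sizes = cystSizes(profiles, r$label)
    )
    if (!is.na(r$sycp3_coverage)) e$sycp3_coverage <- r$sycp3_coverage
    e
  })
  names(out) <- p$label
  out$reference <- referenceLabel(profiles)
  yaml::write_yaml(out, path)
  invisible(path)
}

## Look up one profile row as a list; errors on unknown label.
getProfile <- function(profiles, label) {
  p <- profileTable(profiles)
  i <- match(label, p$label)
  if (is.na(i)) stop("unknown cell-type label: ", label)
  as.list(p[i, ])
}
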