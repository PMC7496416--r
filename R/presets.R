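# Study-condition presets for the synthetic-data generators.
#
# Every preset parameter lives in this one table so the conditions the
# generators emulate are auditable in a single place. Measured quantities
# (affinities, readthrough fractions, motif architecture, selection depth)
# encode the reported wild-type NasR study conditions; amplitudes and noise
# magnitudes are calibration choices of this package, documented in the
# methods vignette.

.presets <- list(
  binding = list(
    "P1P2-nitrate" = list(
      kd = 1, hill_n = 1, bmax = 0.15, x_min = 0.02, x_max = 50,
      x_unit = "uM", noise_cv = 0.05,
      note = "wild-type protein vs the tandem two-hairpin leader RNA with 1 mM nitrate; apparent Kd ~1 uM"),
    "P2-single-hairpin" = list(
      kd = 12, hill_n = 1, bmax = 0.12, x_min = 0.05, x_max = 200,
      x_unit = "uM", noise_cv = 0.05,
      note = "single downstream hairpin with nitrate; ~12-fold poorer affinity (~12 uM)"),
    "unrelated-RNA" = list(
      kd = NA, hill_n = NA, bmax = 0, x_min = 0.02, x_max = 50,
      x_unit = "uM", noise_cv = 0.05,
      note = "similarly sized unrelated hairpin RNA: no detectable binding"),
    "WT-no-nitrate" = list(
      kd = NA, hill_n = NA, bmax = 0, x_min = 0.02, x_max = 50,
      x_unit = "uM", noise_cv = 0.05,
      note = "wild-type protein without nitrate: autoinhibited, no detectable binding"),
    "constitutive-mutant" = list(
      kd = 1.5, hill_n = 1, bmax = 0.15, x_min = 0.02, x_max = 50,
      x_unit = "uM", noise_cv = 0.05,
      note = "interface-decoupled mutant binding without nitrate, near-wild-type affinity (calibration choice)"),
    "ion-nitrate" = list(
      kd = 0.3, hill_n = 1, bmax = 0.12, x_min = 0.003, x_max = 30,
      x_unit = "mM", noise_cv = 0.05,
      note = "nitrate dose response at fixed protein; saturation above 1 mM (half-max placed at 0.3 mM)"),
    "ion-nitrite" = list(
      kd = 0.1, hill_n = 1, bmax = 0.12, x_min = 0.001, x_max = 10,
      x_unit = "uM", noise_cv = 0.05,
      note = "nitrite dose response; saturation above 0.5 uM (half-max placed at 0.1 uM)"),
    "ion-sulfate" = list(
      kd = NA, hill_n = NA, bmax = 0, x_min = 0.003, x_max = 30,
      x_unit = "mM", noise_cv = 0.05,
      note = "non-signal anion control: flat")
  ),
  gel = list(
    "WT-plus-nitrate" = list(
      fraction_ro = 0.52, u_count_T = 25, u_count_RO = 25,
      note = "wild-type protein with 1 mM nitrate: 52% of transcripts bypass the terminator"),
    "WT-minus-nitrate" = list(
      fraction_ro = 0.05, u_count_T = 25, u_count_RO = 25,
      note = "wild-type protein without nitrate: 5% readthrough")
  ),
  selex = list(
    "tandem-hairpin-pool" = list(
      pool_size = 1000, seq_len = 30, rounds = 4, beta = 2,
      epsilon = 0.1, s0 = 8,
      planted_motif = "GGACAUCGCCGUCCAAGGACAUCGCCGUCC",
      planted_frequency = 0.01,
      note = "four selection rounds on random 30-mers; planted tandem hairpin with C:G closing pairs and A1/G4 hexaloops at 1%")
  ),
  alignment = list(
    "NIT-ANTAR-bias" = list(
      n_group = 200, n_rest = 1000, n_columns = 30,
      planted_columns = c(5L, 12L, 19L),
      planted_residues = c("Q", "W", "R"), delta = 0.4,
      group_tag = "NIT-ANTAR", rest_tag = "other",
      note = "sensor-fused group with planted residue bias at three columns over a uniform background")
  )
)

#' List available synthetic-data presets
#'
#' @param modality optional: \code{"binding"}, \code{"gel"},
#'   \code{"selex"} or \code{"alignment"}
#' @return data.frame of preset names, modalities and descriptions
#' @export
listPresets <- function(modality = NULL) {
  mods <- if (is.null(modality)) names(.presets) else modality
  do.call(rbind, lapply(mods, function(m) {
    data.frame(modality = m, preset = names(.presets[[m]]),
               note = vapply(.presets[[m]], `[[`, "", "note"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Parameters of one preset
#'
#' @param modality one of \code{"binding"}, \code{"gel"}, \code{"selex"},
#'   \code{"alignment"}
#' @param preset preset name; unknown names raise an error listing what is
#'   available.
#' @return named list of parameters
#' @export
presetParams <- function(modality, preset) {
  modality <- match.arg(modality, names(.presets))
  pool <- .presets[[modality]]
  if (!preset %in% names(pool))
    stop("unknown ", modality, " preset '", preset, "'; available: ",
         paste(names(pool), collapse = ", "))
  pool[[preset]]
}
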