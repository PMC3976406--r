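#' Reference synthetic study conditions
#'
#' Builds the study configuration used throughout the package's own
#' validation: a 24 x 24 x 16 grid at 3 mm, five networks with single
#' compact spherical cores (radius 9 mm), 8 subjects, 120 volumes at TR
#' 2 s, and — unless `null = TRUE` — an amplitude enhancement (gain 1.5)
#' planted in network 1's core and a suppression (gain 0.6) in network
#' 2's core, both confined to the exhausted condition WD-T3.
#'
#' @param seed integer master seed
#' @param n_subjects subjects (default 8)
#' @param n_networks networks (default 5)
#' @param enh_gain,sup_gain planted WD-T3 gains (defaults 1.5 and 0.6)
#' @param n_vol volumes per scan (default 120)
#' @param dims grid dimensions (default c(24, 24, 16))
#' @param null plant no effects (default FALSE)
#' @param include_wdt2 materialise the WD-T2 scans, which feed only the
#'   regional-score ANCOVA (default TRUE)
#' @return an `rsn_study` whose truth carries the atlas and effects
#' @export
simulate_reference_study <- function(seed, n_subjects = 8, n_networks = 5,
                                     enh_gain = 1.5, sup_gain = 0.6,
                                     n_vol = 120, dims = c(24, 24, 16),
                                     null = FALSE, include_wdt2 = TRUE) {
  grid <- volume_grid(dims)
  atlas <- make_atlas(grid, n_networks, seed = sub_seed(seed, 1),
                      blobs_per_network = 1, core_radius_mm = 9)
  effects <- if (null) list() else list(
    effect_spec(1, which(atlas$core_masks[1, ]),
                c("WD-T3" = enh_gain), atlas = atlas),
    effect_spec(2, which(atlas$core_masks[2, ]),
                c("WD-T3" = sup_gain), atlas = atlas))
  conds <- if (include_wdt2) rsn_conditions() else
    setdiff(rsn_conditions(), "WD-T2")
  simulate_group_study(n_subjects = n_subjects, atlas = atlas,
                       effects = effects, n_vol = n_vol, seed = seed,
                       conditions = conds)
}
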