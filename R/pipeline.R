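#' Run the full ICA pipeline on a simulated study
#'
#' Executes every stage on an `rsn_study`: per-scan preprocessing
#' (high-pass, nuisance regression), per-scan spatial ICA, hierarchical
#' grouping of the baseline (T1) component sets, random-effects cluster
#' t-maps and Bonferroni template masks, goodness-of-fit best-component
#' selection per subject and scan, the combined within-subject contrast
#' per tested network, Monte-Carlo cluster-extent thresholding at
#' `alpha / N` (N = number of tested networks), cluster extraction, and
#' — when regions survive — regional scores for the WD-T2/WD-T3 scans
#' joined with pooled VAS for the scan x exhaustion ANCOVA.
#'
#' Templates are labelled against the generator's true network maps, so
#' recovery can be scored per planted network.
#'
#' @param study an [simulate_group_study()] result
#' @param K components per scan (default: the [select_component_count()]
#'   rule applied to the scan length)
#' @param hp_cycles,physio_order preprocessing parameters
#' @param template_alpha voxel alpha for the Bonferroni template masks
#'   (default 0.05)
#' @param spec the within-subject [contrast_spec()]
#' @param voxel_p two-tailed voxel threshold for the contrast (default 0.01)
#' @param alpha cluster-level alpha before network adjustment (default 0.05)
#' @param networks indices of atlas networks to test (default: all)
#' @param n_networks_adjust divisor N of the network-count adjustment
#'   alpha/N (default: the number of tested networks)
#' @param mc_iter Monte-Carlo iterations (default 500)
#' @param run_ancova fit the regional ANCOVA for surviving clusters
#'   (default TRUE)
#' @param seed integer seed driving ICA initialisations and the
#'   Monte-Carlo thresholds
#' @return list with `component_sets`, `grouping`, `templates`
#'   (per-network), `matching` (network -> cluster table), and per tested
#'   network `results`: contrast `tmap`, estimated `fwhm_mm`, `min_size`,
#'   `clusters`, cluster `report`, `dice` against the planted region (when
#'   one exists for that network), `scores` and `ancova`
#' @export
run_rsn_pipeline <- function(study, K = NULL, hp_cycles = 2,
                             physio_order = 2, template_alpha = 0.05,
                             spec = contrast_spec(), voxel_p = 0.01,
                             alpha = 0.05, networks = NULL,
                             n_networks_adjust = NULL, mc_iter = 500,
                             run_ancova = TRUE, seed = 1L) {
  stopifnot(inherits(study, "rsn_study"))
  grid <- study$grid
  atlas <- study$truth$atlas

  # WD-T2 feeds only the regional-score ANCOVA, never the contrast, so it
  # is decomposed only when the ANCOVA is requested
  wanted <- if (run_ancova) names(study$scans) else
    grep("_WD-T2$", names(study$scans), value = TRUE, invert = TRUE)
  sets <- lapply(seq_along(study$scans), function(i) {
    if (!names(study$scans)[i] %in% wanted) return(NULL)
    sim <- study$scans[[i]]
    scan <- preprocess_scan(sim$scan, sim$confounds, hp_cycles, physio_order)
    decompose_scan(scan, K = K, seed = sub_seed(seed, 500 + i))
  })
  names(sets) <- names(study$scans)
  sets <- Filter(Negate(is.null), sets)

  baseline <- Filter(function(s) s$timepoint == "T1", sets)
  grouping <- hierarchical_group(baseline)

  if (is.null(networks)) networks <- seq_len(nrow(atlas$maps))
  matching <- match_clusters_to_reference(grouping$clusters, atlas$maps)

  templates <- list()
  for (net in networks) {
    cl <- grouping$clusters[[matching$cluster[matching$network == net]]]
    tm <- cluster_tmap(cl)
    templates[[as.character(net)]] <-
      make_template_mask(tm, alpha = template_alpha, n_tests = grid$n_voxels,
                         label = sprintf("network%d", net))
  }

  if (is.null(n_networks_adjust)) n_networks_adjust <- length(networks)
  adj_alpha <- alpha / n_networks_adjust
  effects_by_net <- list()
  for (ef in study$truth$effects)
    effects_by_net[[as.character(ef$target_network)]] <- ef

  beh <- study$behavior
  beh$pooled <- pool_vas(beh$tired_vas, beh$rested_vas)

  results <- list()
  for (net in networks) {
    key <- as.character(net)
    template <- templates[[key]]
    if (!template$usable) {
      results[[key]] <- list(skipped = "unusable template")
      next
    }
    fits <- lapply(sets, select_best_fit, template = template)
    cond_maps <- list()
    for (cond in rsn_conditions()) {
      rows <- Filter(function(f) f$condition == cond, fits)
      if (length(rows) == 0) next
      m <- t(vapply(rows, function(f)
        sets[[paste0(f$subject, "_", cond)]]$maps[f$index, ],
        numeric(grid$n_voxels)))
      rownames(m) <- vapply(rows, function(f) f$subject, character(1))
      cond_maps[[cond]] <- m[order(rownames(m)), , drop = FALSE]
    }
    tmap <- contrast_tmap(cond_maps, spec)
    # smoothness of the fields the t-map is built from: per-subject
    # contrast score maps with the group mean removed (the t ratio map
    # itself is rougher than its ingredients)
    scores <- attr(tmap, "scores")
    resid <- sweep(scores, 2, colMeans(scores))
    fwhm <- mean(apply(resid, 1, estimate_smoothness, grid = grid))
    # null fields coloured by the residual maps' empirical spatial ACF:
    # ICA-derived maps carry heavier-than-Gaussian autocorrelation tails
    # that a scalar FWHM fitted to lag-1 gradients misses
    acf_spec <- estimate_acf_spectrum(resid, grid)
    min_size <- cluster_threshold_mc(grid, fwhm, voxel_p = voxel_p,
                                     alpha = adj_alpha, n_iter = mc_iter,
                                     seed = sub_seed(seed, 700 + net),
                                     acf_spectrum = acf_spec, df = tmap$df)
    clusters <- extract_clusters(tmap, grid, voxel_p = voxel_p,
                                 min_size = as.integer(min_size))

    res <- list(template = template, best_fits = fits, tmap = tmap,
                fwhm_mm = fwhm, min_size = as.integer(min_size),
                clusters = clusters, report = attr(clusters, "report"))

    ef <- effects_by_net[[key]]
    if (!is.null(ef)) {
      sgn <- if (any(ef$condition_gains > 1)) "enhancement" else "suppression"
      same_sign <- Filter(function(cl) cl$sign == sgn, clusters)
      res$dice <- if (length(same_sign) == 0) 0 else
        max(vapply(same_sign, function(cl)
          dice_overlap(cl$voxels, ef$target_region), numeric(1)))
      res$planted_sign <- sgn
    }

    if (run_ancova && length(clusters) > 0) {
      score_scans <- c("WD-T2", "WD-T3")
      entries <- list()
      for (cond in score_scans) {
        rows <- Filter(function(f) f$condition == cond, fits)
        for (f in rows)
          entries[[paste(f$subject, cond)]] <- list(
            subject = f$subject, condition = cond,
            map = sets[[paste0(f$subject, "_", cond)]]$maps[f$index, ])
      }
      res$scores <- lapply(clusters, function(cl) {
        sc <- regional_scores(entries, cl)
        merge(sc, beh[, c("subject", "condition", "pooled")],
              by = c("subject", "condition"))
      })
      res$ancova <- lapply(res$scores, function(sc) {
        tab <- data.frame(subject = sc$subject, scan = sc$condition,
                          score = sc$score, vas = sc$pooled)
        tryCatch(ancova_scores(tab), error = function(e) e$message)
      })
    }
    results[[key]] <- res
  }
  list(component_sets = sets, grouping = grouping, templates = templates,
       matching = matching, adjusted_alpha = adj_alpha, results = results,
       seed = seed)
}
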