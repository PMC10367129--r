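# The concrete classification cascades: liposome identification,
# morphometry, and the reporter modules (gene expression, DNA replication,
# filament formation, membrane relocalization, lipid-probe positivity).
#
# Scale-free cuts (area 8 um2, aspect ratio 0.4) are fixed constants of the
# method. Scale-dependent cuts (focus, texture, intensity) depend on the
# feature implementation and imaging scale, so they ship as presets
# calibrated on labeled synthetic populations; see calibrate_pipelines().

AREA_CUT_UM2 <- 8
ASPECT_RATIO_CUT <- 0.4

#' Calibrate the preset cascades on synthetic populations
#'
#' Generates seed-fixed labeled calibration populations (a morphology
#' mixture and a reporter mixture), extracts features, and derives every
#' scale-dependent cut and two-feature decision rule used by the
#' `classify_*` cascades: the focus cut (gradient RMS), the homogeneity and
#' correlation-texture aggregate rejections, the debris/aggregate intensity
#' split, the circularity sphericity cut, the lamellarity rule
#' (compactness vs max pixel), the rod/doublet rule (H-entropy std vs
#' H-correlation std), the reporter intensity cuts and the blob, filament
#' and relocalization rules.
#'
#' @param optics An [optics_model()].
#' @param n_per_class Calibration events per morphology class. The
#'   rod/doublet and lamellarity boundaries keep improving up to a few
#'   hundred events per class; smaller values are fine for quick runs.
#' @param n_reporter_per_class Calibration events per reporter class (the
#'   reporter cuts separate much more easily, so fewer suffice).
#' @param seed Integer seed for the calibration populations.
#' @param config A [feature_config()].
#' @return An object of class `lg_presets`.
#' @export
calibrate_pipelines <- function(optics = optics_model(), n_per_class = 60,
                                n_reporter_per_class = n_per_class,
                                seed = 20260921,
                                config = feature_config()) {
  morph_classes <- c("sphere", "multilamellar", "rod", "doublet",
                     "aggregate", "debris", "defocused")
  w1 <- stats::setNames(rep(1, length(morph_classes)), morph_classes)
  pop1 <- sample_population(
    population_composition(w1, n_per_class * length(morph_classes),
                           seed = seed),
    optics)
  t1 <- extract_features(pop1$events, config)

  rep_classes <- c("nonexpressing", "expressing", "replication_negative",
                   "replication_homogeneous", "replication_blob",
                   "no_filaments", "filaments", "min_lumen", "min_membrane")
  w2 <- stats::setNames(rep(1, length(rep_classes)), rep_classes)
  pop2 <- sample_population(
    population_composition(w2,
                           n_reporter_per_class * length(rep_classes),
                           seed = seed + 1L),
    optics)
  t2 <- extract_features(pop2$events, config)

  vesicles <- c("sphere", "multilamellar", "rod", "doublet")
  relab <- function(truth, map) {
    tr <- truth
    tr$label <- ifelse(tr$label %in% names(map), map[tr$label], tr$label)
    tr
  }
  grouped1 <- relab(pop1$truth,
                    stats::setNames(rep("vesicle", 4), vesicles))

  presets <- list(
    seed = seed, n_per_class = n_per_class,
    area_cut = AREA_CUT_UM2, aspect_ratio_cut = ASPECT_RATIO_CUT,
    # stage 2: debris vs dense aggregate split among small-area events
    junk_intensity = calibrate_threshold(
      t1[!is.na(t1$area) & t1$area <= AREA_CUT_UM2 + 2, ], pop1$truth,
      "intensity", "aggregate"),
    # stage 3: in-focus vs defocused
    gradient_rms = calibrate_threshold(
      subset_classes(t1, pop1$truth, c("sphere", "defocused")), pop1$truth,
      "gradient_rms", "sphere"),
    # stages 4-5 are safety nets against aggregates that slip through the
    # area/intensity gate: their cuts are placed at a fixed, small false-
    # rejection rate on calibration vesicles rather than at max balanced
    # accuracy, so elongated vesicles (whose textures drift toward the
    # aggregate region) are not sacrificed
    homogeneity = vesicle_guard_threshold(t1, pop1$truth, vesicles,
                                          "h_homogeneity_mean", 0.005),
    corr_texture = calibrate_gate2d(
      t1, grouped1, "h_correlation_mean", "h_correlation_std",
      c("vesicle", "aggregate")),
    corr_margin = NULL,  # filled below
    # morphology
    circularity = calibrate_threshold(
      subset_classes(t1, pop1$truth,
                     c("sphere", "multilamellar", "rod", "doublet")),
      relab(pop1$truth, c(sphere = "spherical",
                          multilamellar = "spherical")),
      "circularity", "spherical"),
    lamellarity = calibrate_gate2d(
      t1, pop1$truth, "compactness", "max_pixel",
      c("sphere", "multilamellar"), quadratic = TRUE),
    rod_doublet = calibrate_gate2d(
      t1, pop1$truth, "h_entropy_std", "h_correlation_std",
      c("rod", "doublet"), quadratic = TRUE),
    # reporter modules
    expression_intensity = calibrate_threshold(
      subset_classes(t2, pop2$truth, c("nonexpressing", "expressing")),
      pop2$truth, "reporter_intensity", "expressing"),
    replication_intensity = calibrate_threshold(
      subset_classes(t2, pop2$truth,
                     c("replication_negative", "replication_homogeneous",
                       "replication_blob")),
      relab(pop2$truth, c(replication_homogeneous = "replication_positive",
                          replication_blob = "replication_positive")),
      "reporter_intensity", "replication_positive"),
    blob = calibrate_gate2d(
      t2, pop2$truth, "reporter_std_dev", "reporter_h_homogeneity_mean",
      c("replication_blob", "replication_homogeneous")),
    filament_intensity = calibrate_threshold(
      subset_classes(t2, pop2$truth, c("nonexpressing", "filaments",
                                       "no_filaments")),
      relab(pop2$truth, c(filaments = "bright", no_filaments = "bright")),
      "reporter_intensity", "bright"),
    filament = calibrate_gate2d(
      t2, pop2$truth, "reporter_std_dev", "reporter_contrast",
      c("filaments", "no_filaments")),
    reloc_quality = calibrate_gate2d(
      t1, pop1$truth, "h_correlation_std", "h_contrast_std",
      c("sphere", "multilamellar")),
    bds = calibrate_threshold(
      subset_classes(t2, pop2$truth, c("min_lumen", "min_membrane")),
      pop2$truth, "bds_r3", "min_membrane")
  )
  # stage-5 margin: trigger only beyond the 99.5% margin quantile of every
  # vesicle subtype (rods sit closest to the aggregate texture region and
  # must not be sacrificed)
  presets$corr_margin <- max(vapply(vesicles, function(cl) {
    sub <- subset_classes(t1, pop1$truth, cl)
    sc <- gate2d_scores(presets$corr_texture, sub)
    stats::quantile(sc[, "vesicle"] - sc[, "aggregate"], 0.9975,
                    names = FALSE, na.rm = TRUE)
  }, numeric(1)))
  # relocalization quality gate: exclude only events clearly beyond the
  # unilamellar-sphere margin in the (H-correlation std, H-contrast std)
  # plane
  sph <- subset_classes(t1, pop1$truth, "sphere")
  scq <- gate2d_scores(presets$reloc_quality, sph)
  presets$reloc_margin <- stats::quantile(
    scq[, "sphere"] - scq[, "multilamellar"], 0.995, names = FALSE,
    na.rm = TRUE)
  structure(presets, class = "lg_presets")
}

# one-sided guard: pass if the feature is above the q-quantile of every
# vesicle subtype (small fixed false-rejection rate per shape class, so no
# single class — rods have the lowest homogeneity — is sacrificed)
vesicle_guard_threshold <- function(table, truth, classes, feature, q) {
  lab <- truth$label[match(table$event_id, truth$event_id)]
  cut <- min(vapply(classes, function(cl)
    stats::quantile(table[[feature]][lab == cl], q, names = FALSE,
                    na.rm = TRUE), numeric(1)))
  structure(list(threshold = cut, direction = ">",
                 balanced_accuracy = NA_real_,
                 feature = feature, positive_class = "vesicle"),
            class = "lg_threshold")
}

subset_classes <- function(table, truth, classes) {
  lab <- truth$label[match(table$event_id, truth$event_id)]
  table[lab %in% classes, , drop = FALSE]
}

#' @export
print.lg_presets <- function(x, ...) {
  cat("<lg_presets> calibrated cascade presets\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (inherits(v, "lg_threshold"))
      cat(sprintf("  %-22s %s %s %.4g (BA %.3f)\n", nm, v$feature,
                  v$direction, v$threshold, v$balanced_accuracy))
    else if (inherits(v, "lg_gate2d"))
      cat(sprintf("  %-22s (%s, %s) -> %s\n", nm, v$fx, v$fy,
                  paste(v$classes, collapse = "|")))
  }
  invisible(x)
}

pass_threshold <- function(values, thr) {
  res <- switch(thr$direction,
                ">" = values > thr$threshold,
                "<" = values < thr$threshold)
  res & !is.na(res)
}

#' Liposome identification cascade
#'
#' Sequentially separates well-resolved, in-focus, isolated liposomes
#' ("good") from debris, dense aggregates and out-of-focus objects:
#' (1) area > 8 um2 and aspect ratio > 0.4; (2) small-area events are
#' labeled debris (low membrane intensity) or dense aggregate (high
#' intensity); (3) events below the calibrated gradient-RMS focus cut are
#' out of focus; (4) events below the calibrated H-homogeneity cut and
#' (5) events in the aggregate region of the (H-correlation mean,
#' H-correlation std) plane are aggregates. Events whose mask is empty are
#' sub-resolution objects and are labeled debris.
#'
#' @param table Feature table from [extract_features()].
#' @param presets An `lg_presets` from [calibrate_pipelines()].
#' @return A labels data.frame: `event_id`, `identification` in
#'   good_liposome / debris / aggregate / out_of_focus / rejected.
#' @export
identify_liposomes <- function(table, presets) {
  stopifnot(inherits(presets, "lg_presets"))
  n <- nrow(table)
  ident <- rep("good_liposome", n)

  small <- !is.na(table$area) & table$area <= presets$area_cut
  empty <- table$mask_empty | is.na(table$area)
  oblong <- !is.na(table$aspect_ratio) &
    table$aspect_ratio <= presets$aspect_ratio_cut

  # stages 1-2: resolution/shape cut, then the (area, intensity) regions
  dense <- pass_threshold(table$intensity, presets$junk_intensity)
  ident[small & dense] <- "aggregate"
  ident[small & !dense] <- "debris"
  ident[empty] <- "debris"
  ident[!small & !empty & oblong] <- "rejected"

  alive <- ident == "good_liposome"
  # stage 3: focus
  blur <- alive & !pass_threshold(table$gradient_rms, presets$gradient_rms)
  ident[blur] <- "out_of_focus"
  alive <- alive & !blur
  # stage 4: homogeneity
  agg4 <- alive & !pass_threshold(table$h_homogeneity_mean,
                                  presets$homogeneity)
  ident[agg4] <- "aggregate"
  alive <- alive & !agg4
  # stage 5: correlation-texture region (margin beyond the vesicle guard)
  sc <- gate2d_scores(presets$corr_texture, table)
  margin <- sc[, "vesicle"] - sc[, "aggregate"]
  agg5 <- alive & !is.na(margin) & margin > presets$corr_margin
  ident[agg5] <- "aggregate"

  data.frame(event_id = table$event_id, identification = ident,
             stringsAsFactors = FALSE)
}

#' Morphological classification of identified liposomes
#'
#' Splits good liposomes into spherical and nonspherical on the calibrated
#' circularity cut; spherical liposomes into unilamellar and
#' multilamellar/multivesicular in the (compactness, max pixel) plane; and
#' nonspherical liposomes into rod-shaped and doublets in the
#' (H-entropy std, H-correlation std) plane. Events that are not good
#' liposomes stay `unclassified`.
#'
#' @param table Feature table.
#' @param labels Labels from [identify_liposomes()].
#' @param presets An `lg_presets`.
#' @return `labels` with a `morphology` column: spherical_unilamellar,
#'   spherical_multilamellar, rod, doublet, nonspherical_other,
#'   unclassified.
#' @export
classify_morphology <- function(table, labels, presets) {
  stopifnot(identical(table$event_id, labels$event_id))
  n <- nrow(table)
  morph <- rep("unclassified", n)
  good <- labels$identification == "good_liposome"

  spher <- good & pass_threshold(table$circularity, presets$circularity)
  nonspher <- good & !spher

  lam <- predict(presets$lamellarity, table)
  morph[spher & !is.na(lam) & lam == "sphere"] <- "spherical_unilamellar"
  morph[spher & !is.na(lam) & lam == "multilamellar"] <-
    "spherical_multilamellar"
  morph[spher & is.na(lam)] <- "spherical_unilamellar"

  rd <- predict(presets$rod_doublet, table)
  morph[nonspher & !is.na(rd) & rd == "rod"] <- "rod"
  morph[nonspher & !is.na(rd) & rd == "doublet"] <- "doublet"
  morph[nonspher & is.na(rd)] <- "nonspherical_other"

  labels$morphology <- morph
  labels
}

#' Gene-expression classification (lumen reporter intensity)
#'
#' Good liposomes with background-subtracted reporter intensity above the
#' threshold are `expressing`, the rest `nonexpressing`; other events stay
#' `NA`.
#'
#' @param table Feature table.
#' @param labels Labels with an `identification` column.
#' @param threshold Intensity threshold (a.u.); e.g.
#'   `presets$expression_intensity$threshold` or a value derived with
#'   [threshold_from_negative()].
#' @return `labels` with an `expression` column.
#' @export
classify_expression <- function(table, labels, threshold) {
  stopifnot(identical(table$event_id, labels$event_id))
  good <- labels$identification == "good_liposome"
  expr <- rep(NA_character_, nrow(table))
  pos <- !is.na(table$reporter_intensity) &
    table$reporter_intensity > threshold
  expr[good & pos] <- "expressing"
  expr[good & !pos] <- "nonexpressing"
  labels$expression <- expr
  labels
}

#' Size statistics of expressing vs nonexpressing liposomes
#'
#' @param table Feature table.
#' @param labels Labels with an `expression` column.
#' @return data.frame with per-group n, mean/sd diameter and area, plus
#'   attribute `area_intensity_cor`: Pearson correlation of area and
#'   reporter intensity among expressing liposomes.
#' @export
expression_stats <- function(table, labels) {
  groups <- c("expressing", "nonexpressing")
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- !is.na(labels$expression) & labels$expression == g
    data.frame(group = g, n = sum(sel),
               mean_diameter = mean(table$diameter[sel]),
               sd_diameter = stats::sd(table$diameter[sel]),
               mean_area = mean(table$area[sel]),
               stringsAsFactors = FALSE)
  }))
  sel <- !is.na(labels$expression) & labels$expression == "expressing"
  attr(out, "area_intensity_cor") <-
    if (sum(sel) > 2) stats::cor(table$area[sel],
                                 table$reporter_intensity[sel])
    else NA_real_
  out
}

#' DNA-replication classification (negative / homogeneous / blob)
#'
#' Good liposomes below the reporter intensity cut are replication
#' `negative`; the rest are split into `homogeneous` lumen signal vs a
#' condensed replication `blob` in the (std dev, H-homogeneity mean) plane
#' of the reporter channel.
#'
#' @param table Feature table.
#' @param labels Labels with `identification`.
#' @param presets An `lg_presets`.
#' @param threshold Intensity cut; defaults to the calibrated preset.
#' @return `labels` with a `replication` column.
#' @export
classify_replication <- function(table, labels, presets,
                                 threshold = NULL) {
  stopifnot(identical(table$event_id, labels$event_id))
  if (is.null(threshold))
    threshold <- presets$replication_intensity$threshold
  good <- labels$identification == "good_liposome"
  out <- rep(NA_character_, nrow(table))
  pos <- !is.na(table$reporter_intensity) &
    table$reporter_intensity > threshold
  out[good & !pos] <- "negative"
  cls <- predict(presets$blob, table)
  out[good & pos] <- ifelse(
    !is.na(cls[good & pos]) & cls[good & pos] == "replication_blob",
    "blob", "homogeneous")
  labels$replication <- out
  labels
}

#' Filament (bacterial microtubule) classification
#'
#' Good liposomes below the reporter intensity cut are excluded
#' (`below_intensity`); the rest are split into `filament` vs `no_filament`
#' in the (std dev, contrast) plane of the reporter channel — filament
#' bundles are thin sharp structures with high std dev and high contrast.
#'
#' @inheritParams classify_replication
#' @return `labels` with a `filament` column.
#' @export
classify_filaments <- function(table, labels, presets, threshold = NULL) {
  stopifnot(identical(table$event_id, labels$event_id))
  if (is.null(threshold))
    threshold <- presets$filament_intensity$threshold
  good <- labels$identification == "good_liposome"
  out <- rep(NA_character_, nrow(table))
  pos <- !is.na(table$reporter_intensity) &
    table$reporter_intensity > threshold
  out[good & !pos] <- "below_intensity"
  cls <- predict(presets$filament, table)
  out[good & pos] <- ifelse(
    !is.na(cls[good & pos]) & cls[good & pos] == "filaments",
    "filament", "no_filament")
  labels$filament <- out
  labels
}

#' Membrane-relocalization classification
#'
#' Applies an extra unilamellarity quality gate in the membrane channel
#' ((H-correlation std, H-contrast std) region) to discard events with
#' internal membrane structures, then classifies the survivors by the
#' bright-detail similarity of the membrane and reporter channels: events
#' above the calibrated cut have reporter signal colocalized with the
#' membrane (`membrane_localized`, i.e. active relocalization), the rest
#' are `lumen_localized`. Gated-out events are `excluded`.
#'
#' @inheritParams classify_replication
#' @param bds_cut Bright-detail-similarity cut; defaults to the calibrated
#'   preset.
#' @return `labels` with a `relocalization` column.
#' @export
classify_relocalization <- function(table, labels, presets,
                                    bds_cut = NULL) {
  stopifnot(identical(table$event_id, labels$event_id))
  if (is.null(bds_cut)) bds_cut <- presets$bds$threshold
  good <- labels$identification == "good_liposome"
  out <- rep(NA_character_, nrow(table))
  scq <- gate2d_scores(presets$reloc_quality, table)
  margin <- scq[, "sphere"] - scq[, "multilamellar"]
  excl <- good & !is.na(margin) & margin > presets$reloc_margin
  out[excl] <- "excluded"
  keep <- good & !excl
  pos <- !is.na(table$bds_r3) & table$bds_r3 > bds_cut
  out[keep & pos] <- "membrane_localized"
  out[keep & !pos] <- "lumen_localized"
  labels$relocalization <- out
  labels
}

#' Lipid-probe positivity against a negative control
#'
#' Sets the positivity threshold from the negative-control sample's
#' membrane-probe (reporter) intensities via [threshold_from_negative()],
#' labels positive-sample good liposomes above it as `ps_positive`, and
#' reports the false-positive rate achieved on the negative sample itself.
#'
#' @param positive_table Feature table of the probe-stained sample.
#' @param negative_table Feature table of the control lacking the enzyme
#'   gene.
#' @param labels Labels for `positive_table` (from
#'   [identify_liposomes()]).
#' @param max_fpr Tolerated false-positive fraction on the negative
#'   control.
#' @param negative_labels Optional labels for the negative table; if given,
#'   only its good liposomes enter the threshold estimate.
#' @return List with `labels` (a `ps` column added: ps_positive /
#'   ps_negative / NA), `threshold`, `negative_fpr`.
#' @export
classify_ps <- function(positive_table, negative_table, labels,
                        max_fpr = 0.05, negative_labels = NULL) {
  stopifnot(identical(positive_table$event_id, labels$event_id))
  if (nrow(negative_table) == 0L)
    stop("negative control table is empty", call. = FALSE)
  neg_vals <- negative_table$reporter_intensity
  if (!is.null(negative_labels))
    neg_vals <- neg_vals[negative_labels$identification == "good_liposome"]
  thr <- threshold_from_negative(neg_vals, max_fpr)
  good <- labels$identification == "good_liposome"
  out <- rep(NA_character_, nrow(positive_table))
  pos <- !is.na(positive_table$reporter_intensity) &
    positive_table$reporter_intensity > thr
  out[good & pos] <- "ps_positive"
  out[good & !pos] <- "ps_negative"
  labels$ps <- out
  list(labels = labels, threshold = thr,
       negative_fpr = mean(neg_vals > thr, na.rm = TRUE))
}

#' Population summary of labeled events
#'
#' Counts and fractions per label at every labeling level present
#' (identification, morphology, expression, replication, filament,
#' relocalization, ps), plus per-class diameter statistics (mean, sd,
#' fraction below a size cut).
#'
#' @param labels Labels data.frame.
#' @param table Feature table.
#' @param size_cut Diameter cut (um) for the small-liposome fraction.
#' @return An object of class `lg_population_summary`.
#' @export
population_summary <- function(labels, table, size_cut = 10) {
  stopifnot(identical(table$event_id, labels$event_id))
  levels_ <- intersect(c("identification", "morphology", "expression",
                         "replication", "filament", "relocalization", "ps"),
                       names(labels))
  out <- list(n_events = nrow(labels), size_cut = size_cut)
  for (lv in levels_) {
    lab <- labels[[lv]]
    keep <- !is.na(lab)
    cnt <- table(lab[keep])
    stats_ <- do.call(rbind, lapply(names(cnt), function(cl) {
      sel <- keep & lab == cl
      d <- table$diameter[sel]
      data.frame(label = cl, n = sum(sel),
                 fraction = sum(sel) / sum(keep),
                 mean_diameter = mean(d, na.rm = TRUE),
                 sd_diameter = stats::sd(d),
                 frac_below_cut = mean(d < size_cut, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    out[[lv]] <- stats_
  }
  structure(out, class = "lg_population_summary")
}

#' @export
print.lg_population_summary <- function(x, ...) {
  cat(sprintf("<population summary> %d events (size cut %.3g um)\n",
              x$n_events, x$size_cut))
  for (lv in setdiff(names(x), c("n_events", "size_cut"))) {
    cat("--", lv, "--\n")
    df <- x[[lv]]
    df$fraction <- sprintf("%.1f%%", 100 * df$fraction)
    print(df, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
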