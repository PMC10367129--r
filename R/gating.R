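# Declarative gates over feature tables and ordered gating pipelines with
# per-stage accounting. All gates are per-event: membership depends only on
# the event's own feature row, so permuting stages never changes the final
# selected set (only the per-stage bookkeeping).

#' Declarative gates on one or two features
#'
#' A gate is a named selection rule over a feature table:
#' * `gate_threshold()` — one-sided cut on one feature (`>` `>=` `<` `<=`);
#' * `gate_interval()` — closed interval on one feature;
#' * `gate_rect()` — axis-aligned rectangle on a feature pair;
#' * `gate_polygon()` — convex or simple polygon on a feature pair
#'   (even-odd rule, boundary counted inside);
#' * `gate_expr()` — arbitrary predicate expression over feature columns,
#'   for combined cuts.
#'
#' Any gate can be negated with `negate = TRUE` (select the complement).
#' Rows with undefined (`NA`) features always fail a gate, whatever
#' `negate` says; they are tallied separately by [evaluate_gate()] and
#' [run_pipeline()], mirroring the silent exclusion of unanalyzable objects
#' from manual gating.
#'
#' @param name Stage/gate name.
#' @param feature,fx,fy Feature column name(s).
#' @param cut Threshold value.
#' @param direction One of `">"`, `">="`, `"<"`, `"<="`.
#' @param lo,hi Interval bounds (`lo <= hi`).
#' @param xlim,ylim Rectangle bounds, each length-2 ascending.
#' @param vx,vy Polygon vertex coordinates (equal length >= 3).
#' @param expr A one-sided formula, e.g. `~ area > 8 & aspect_ratio > 0.4`.
#' @param negate Select the complement instead.
#' @return An object of class `lg_gate`.
#' @examples
#' g <- gate_threshold("big", "area", 8, ">")
#' evaluate_gate(data.frame(area = c(4, 9, 12)), g)
#' @export
gate_threshold <- function(name, feature, cut,
                           direction = c(">", ">=", "<", "<="),
                           negate = FALSE) {
  direction <- match.arg(direction)
  new_gate(name, "threshold", feature,
           list(cut = cut, direction = direction), negate)
}

#' @rdname gate_threshold
#' @export
gate_interval <- function(name, feature, lo, hi, negate = FALSE) {
  if (!(lo <= hi)) stop("interval bounds must be ordered", call. = FALSE)
  new_gate(name, "interval", feature, list(lo = lo, hi = hi), negate)
}

#' @rdname gate_threshold
#' @export
gate_rect <- function(name, fx, fy, xlim, ylim, negate = FALSE) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L)
  if (xlim[1] > xlim[2] || ylim[1] > ylim[2])
    stop("rectangle bounds must be ordered", call. = FALSE)
  new_gate(name, "rect", c(fx, fy), list(xlim = xlim, ylim = ylim), negate)
}

#' @rdname gate_threshold
#' @export
gate_polygon <- function(name, fx, fy, vx, vy, negate = FALSE) {
  stopifnot(length(vx) == length(vy), length(vx) >= 3L)
  new_gate(name, "polygon", c(fx, fy), list(vx = vx, vy = vy), negate)
}

#' @rdname gate_threshold
#' @export
gate_expr <- function(name, expr, negate = FALSE) {
  stopifnot(inherits(expr, "formula"), length(expr) == 2L)
  vars <- all.vars(expr[[2]])
  new_gate(name, "expr", vars, list(expr = expr[[2]]), negate)
}

new_gate <- function(name, type, features, params, negate) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, type = type, features = features,
                 params = params, negate = isTRUE(negate)),
            class = "lg_gate")
}

#' @export
print.lg_gate <- function(x, ...) {
  cat(sprintf("<gate '%s'> %s on %s%s\n", x$name, x$type,
              paste(x$features, collapse = ", "),
              if (x$negate) " (negated)" else ""))
  invisible(x)
}

point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  # count boundary points as inside (vertex / horizontal-edge cases)
  on_vertex <- rep(FALSE, length(px))
  for (i in seq_len(n)) on_vertex <- on_vertex | (px == vx[i] & py == vy[i])
  inside | on_vertex
}

#' Evaluate one gate on a feature table
#'
#' @param table Feature table (data.frame), one row per event.
#' @param gate An `lg_gate`.
#' @return Logical vector, one flag per row; rows with undefined (`NA`)
#'   features get `FALSE`. The count of such rows is attached as attribute
#'   `n_undefined`.
#' @export
evaluate_gate <- function(table, gate) {
  stopifnot(inherits(gate, "lg_gate"), is.data.frame(table))
  missing_f <- setdiff(gate$features, names(table))
  if (length(missing_f))
    stop("gate '", gate$name, "' references unknown feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0L)
    return(structure(logical(0), n_undefined = 0L))
  p <- gate$params
  raw <- switch(gate$type,
    threshold = {
      v <- table[[gate$features]]
      switch(p$direction, ">" = v > p$cut, ">=" = v >= p$cut,
             "<" = v < p$cut, "<=" = v <= p$cut)
    },
    interval = {
      v <- table[[gate$features]]
      v >= p$lo & v <= p$hi
    },
    rect = {
      x <- table[[gate$features[1]]]; y <- table[[gate$features[2]]]
      x >= p$xlim[1] & x <= p$xlim[2] & y >= p$ylim[1] & y <= p$ylim[2]
    },
    polygon = {
      x <- table[[gate$features[1]]]; y <- table[[gate$features[2]]]
      res <- point_in_polygon(x, y, p$vx, p$vy)
      res[is.na(x) | is.na(y)] <- NA
      res
    },
    expr = eval(p$expr, envir = table, enclos = baseenv()))
  if (gate$negate) raw <- !raw
  und <- is.na(raw)
  raw[und] <- FALSE
  structure(as.logical(raw), n_undefined = sum(und))
}

#' Ordered gating pipeline
#'
#' @param stages List of `lg_gate` objects; stage names must be unique.
#' @param label Label of the input population.
#' @return An object of class `lg_pipeline`.
#' @export
gating_pipeline <- function(stages, label = "events") {
  if (inherits(stages, "lg_gate")) stages <- list(stages)
  stopifnot(length(stages) >= 1L,
            all(vapply(stages, inherits, logical(1), "lg_gate")))
  nm <- vapply(stages, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("stage names must be unique", call. = FALSE)
  structure(list(stages = stages, label = label), class = "lg_pipeline")
}

#' Run a gating pipeline with per-stage accounting
#'
#' Stages are applied in order to the surviving subset. At every stage,
#' `passing + failing + undefined = entering`, and the product of the stage
#' pass fractions equals the final pass fraction.
#'
#' @param table Feature table.
#' @param pipeline An [gating_pipeline()].
#' @return An object of class `lg_gating_result`: list with `stages`
#'   (data.frame: stage, n_in, n_pass, n_fail, n_undefined, fraction),
#'   `membership` (logical matrix event x stage, cumulative), `final`
#'   (logical vector), `label`.
#' @export
run_pipeline <- function(table, pipeline) {
  stopifnot(inherits(pipeline, "lg_pipeline"))
  n <- nrow(table)
  k <- length(pipeline$stages)
  alive <- rep(TRUE, n)
  membership <- matrix(FALSE, n, k)
  nm <- vapply(pipeline$stages, `[[`, character(1), "name")
  colnames(membership) <- nm
  acc <- data.frame(stage = nm, n_in = NA_integer_, n_pass = NA_integer_,
                    n_fail = NA_integer_, n_undefined = NA_integer_,
                    fraction = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    sub <- table[alive, , drop = FALSE]
    flags <- evaluate_gate(sub, pipeline$stages[[i]])
    n_in <- sum(alive)
    pass <- logical(n)
    pass[alive] <- flags
    acc$n_in[i] <- n_in
    acc$n_pass[i] <- sum(pass)
    acc$n_undefined[i] <- attr(flags, "n_undefined")
    acc$n_fail[i] <- n_in - sum(pass) - acc$n_undefined[i]
    acc$fraction[i] <- if (n_in > 0) sum(pass) / n_in else NA_real_
    alive <- pass
    membership[, i] <- alive
  }
  structure(list(stages = acc, membership = membership, final = alive,
                 label = pipeline$label),
            class = "lg_gating_result")
}

#' @export
print.lg_gating_result <- function(x, ...) {
  cat(sprintf("<gating result> population '%s': %d -> %d events\n",
              x$label, if (nrow(x$stages)) x$stages$n_in[1] else 0L,
              sum(x$final)))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Cumulative fraction across sequential gating stages
#'
#' The fraction of the starting population surviving a cascade is the
#' product of the per-stage pass fractions (e.g. 6% identified liposomes
#' of which 45% spherical of which 58% unilamellar gives about 1.6%).
#'
#' @param stage_fractions Numeric vector of fractions in `[0, 1]`.
#' @return Their product (1 for an empty vector).
#' @examples
#' cumulative_fraction(c(0.06, 0.45, 0.58))
#' @export
cumulative_fraction <- function(stage_fractions) {
  if (length(stage_fractions) == 0L) return(1)
  if (any(!is.finite(stage_fractions)) ||
      any(stage_fractions < 0 | stage_fractions > 1))
    stop("stage fractions must lie in [0, 1]", call. = FALSE)
  prod(stage_fractions)
}

#' Positivity threshold from a negative control
#'
#' Returns the empirical `1 - max_fpr` quantile (type 1, i.e. an observed
#' order statistic) of the negative-control values, so that the fraction of
#' negative events strictly above the threshold is at most `max_fpr`.
#'
#' @param negative_values Numeric vector from the negative-control sample.
#' @param max_fpr Tolerated false-positive fraction, in (0, 1).
#' @return The threshold value.
#' @examples
#' threshold_from_negative(1:100, 0.05)
#' @export
threshold_from_negative <- function(negative_values, max_fpr = 0.05) {
  negative_values <- negative_values[!is.na(negative_values)]
  if (!length(negative_values))
    stop("negative control sample is empty", call. = FALSE)
  if (!is.numeric(max_fpr) || max_fpr <= 0 || max_fpr >= 1)
    stop("max_fpr must lie in (0, 1)", call. = FALSE)
  stats::quantile(negative_values, 1 - max_fpr, type = 1, names = FALSE)
}

#' Calibrate a one-feature threshold on labeled data
#'
#' Scans all candidate cuts (midpoints between consecutive sorted unique
#' values) in both directions and returns the cut maximizing balanced
#' accuracy (mean of sensitivity and specificity) for separating
#' `positive_class` from the rest. Replaces hand-drawn one-dimensional
#' gates when ground truth (or a labeled calibration sample) is available.
#'
#' @param table Feature table with an `event_id` column.
#' @param truth Truth table with `event_id` and `label` columns.
#' @param feature Feature column to threshold.
#' @param positive_class Label treated as positive.
#' @return An object of class `lg_threshold`: list with `threshold`,
#'   `direction` (`">"` means positives lie above), `balanced_accuracy`.
#' @export
calibrate_threshold <- function(table, truth, feature, positive_class) {
  stopifnot(feature %in% names(table))
  lab <- truth$label[match(table$event_id, truth$event_id)]
  v <- table[[feature]]
  ok <- !is.na(v) & !is.na(lab)
  v <- v[ok]; pos <- lab[ok] == positive_class
  if (!any(pos) || all(pos))
    stop("calibration needs both classes present", call. = FALSE)
  o <- order(v)
  v <- v[o]; pos <- pos[o]
  npos <- sum(pos); nneg <- sum(!pos)
  # candidate cut after position i: positives above => TP = npos - cum_pos[i]
  cum_pos <- cumsum(pos); cum_neg <- cumsum(!pos)
  uniq_end <- which(diff(v) > 0)        # cut between v[i] and v[i+1]
  if (!length(uniq_end))
    stop("feature is constant; cannot calibrate", call. = FALSE)
  tpr_up <- (npos - cum_pos[uniq_end]) / npos
  tnr_up <- cum_neg[uniq_end] / nneg
  ba_up <- (tpr_up + tnr_up) / 2
  ba_dn <- (cum_pos[uniq_end] / npos + (nneg - cum_neg[uniq_end]) / nneg) / 2
  cuts <- (v[uniq_end] + v[uniq_end + 1L]) / 2
  i_up <- which.max(ba_up); i_dn <- which.max(ba_dn)
  if (ba_up[i_up] >= ba_dn[i_dn]) {
    res <- list(threshold = cuts[i_up], direction = ">",
                balanced_accuracy = ba_up[i_up])
  } else {
    res <- list(threshold = cuts[i_dn], direction = "<",
                balanced_accuracy = ba_dn[i_dn])
  }
  res$feature <- feature
  res$positive_class <- positive_class
  structure(res, class = "lg_threshold")
}

#' @export
print.lg_threshold <- function(x, ...) {
  cat(sprintf("<threshold> %s %s %.4g (balanced accuracy %.3f, positive: %s)\n",
              x$feature, x$direction, x$threshold, x$balanced_accuracy,
              x$positive_class))
  invisible(x)
}

#' Calibrate a two-feature discriminant gate on labeled data
#'
#' Gaussian discriminant rule in a feature plane — the programmatic
#' replacement for a hand-drawn two-dimensional gate. With
#' `quadratic = FALSE` the pooled within-class covariance is used
#' (linear discriminant analysis with equal priors; decision regions are
#' half-planes or convex cells); with `quadratic = TRUE` each class keeps
#' its own covariance (QDA; conic boundaries), which helps when class
#' spreads differ. For two classes, the decision offset along the score
#' difference is additionally chosen to maximize the smaller of the two
#' per-class recalls, estimated on 5-fold out-of-fold margins, so neither
#' class is systematically sacrificed.
#'
#' @param table Feature table with `event_id`.
#' @param truth Truth table with `event_id`, `label`.
#' @param fx,fy Feature columns.
#' @param classes Character vector of class labels to discriminate.
#' @param quadratic Per-class covariances instead of the pooled one.
#' @return An object of class `lg_gate2d` with `predict()` support.
#' @export
calibrate_gate2d <- function(table, truth, fx, fy, classes,
                             quadratic = FALSE) {
  lab <- truth$label[match(table$event_id, truth$event_id)]
  x <- table[[fx]]; y <- table[[fy]]
  ok <- !is.na(x) & !is.na(y) & lab %in% classes
  if (length(unique(lab[ok])) < 2L)
    stop("calibration needs at least two classes present", call. = FALSE)
  reg <- function(s) s + diag(2) * 1e-8 * max(diag(s), 1e-12)
  means <- list(); covs <- list()
  sw <- matrix(0, 2, 2); ntot <- 0L
  for (cl in classes) {
    sel <- ok & lab == cl
    m <- cbind(x[sel], y[sel])
    means[[cl]] <- colMeans(m)
    if (nrow(m) > 1) {
      covs[[cl]] <- reg(stats::cov(m))
      sw <- sw + stats::cov(m) * (nrow(m) - 1)
      ntot <- ntot + nrow(m) - 1L
    }
  }
  sw <- reg(sw / max(ntot, 1L))
  if (!quadratic) covs <- lapply(means, function(...) sw)
  inv <- lapply(covs, solve)
  logdet <- vapply(covs, function(s) determinant(s)$modulus[1], numeric(1))
  obj <- structure(list(fx = fx, fy = fy, classes = classes, means = means,
                        inv = inv, logdet = logdet, quadratic = quadratic,
                        offset = 0),
                   class = "lg_gate2d")
  if (length(classes) == 2L) {
    # shift the two-class boundary to the point that maximizes the smaller
    # of the two per-class recalls (minimax), so neither class is
    # systematically sacrificed; margins are estimated out-of-fold so the
    # offset is not biased by resubstitution optimism
    sub <- table[ok, , drop = FALSE]
    lab_ok <- lab[ok]
    n_ok <- nrow(sub)
    fold <- (seq_len(n_ok) - 1L) %% 5L + 1L
    margin <- numeric(n_ok)
    for (f in 1:5) {
      tr_idx <- fold != f
      g_f <- suppressWarnings(tryCatch(
        calibrate_gate2d_core(sub[tr_idx, , drop = FALSE],
                              lab_ok[tr_idx], fx, fy, classes, quadratic),
        error = function(e) NULL))
      sc_f <- gate2d_scores(if (is.null(g_f)) obj else g_f,
                            sub[!tr_idx, , drop = FALSE])
      margin[!tr_idx] <- sc_f[, 1] - sc_f[, 2]  # > 0 favors class 2
    }
    cand <- sort(unique(margin))
    cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
              cand[length(cand)] + 1)
    rec1 <- vapply(cand, function(t)
      mean(margin[lab_ok == classes[1]] <= t), numeric(1))
    rec2 <- vapply(cand, function(t)
      mean(margin[lab_ok == classes[2]] > t), numeric(1))
    obj$offset <- cand[which.max(pmin(rec1, rec2))]
  }
  obj
}

# fit the per-class Gaussian discriminant pieces from raw vectors (no
# offset search); used for the cross-validated offset above
calibrate_gate2d_core <- function(table, lab, fx, fy, classes, quadratic) {
  x <- table[[fx]]; y <- table[[fy]]
  ok <- !is.na(x) & !is.na(y)
  reg <- function(s) s + diag(2) * 1e-8 * max(diag(s), 1e-12)
  means <- list(); covs <- list()
  sw <- matrix(0, 2, 2); ntot <- 0L
  for (cl in classes) {
    sel <- ok & lab == cl
    if (sum(sel) < 3) stop("too few calibration events for ", cl)
    m <- cbind(x[sel], y[sel])
    means[[cl]] <- colMeans(m)
    covs[[cl]] <- reg(stats::cov(m))
    sw <- sw + stats::cov(m) * (nrow(m) - 1)
    ntot <- ntot + nrow(m) - 1L
  }
  sw <- reg(sw / max(ntot, 1L))
  if (!quadratic) covs <- lapply(means, function(...) sw)
  structure(list(fx = fx, fy = fy, classes = classes, means = means,
                 inv = lapply(covs, solve),
                 logdet = vapply(covs, function(s)
                   determinant(s)$modulus[1], numeric(1)),
                 quadratic = quadratic, offset = 0),
            class = "lg_gate2d")
}

# per-class discriminant scores (lower = closer); matrix n x classes
gate2d_scores <- function(object, table) {
  x <- table[[object$fx]]; y <- table[[object$fy]]
  sc <- vapply(object$classes, function(cl) {
    dx <- x - object$means[[cl]][1]; dy <- y - object$means[[cl]][2]
    A <- object$inv[[cl]]
    A[1, 1] * dx^2 + 2 * A[1, 2] * dx * dy + A[2, 2] * dy^2 +
      object$logdet[cl]
  }, numeric(length(x)))
  matrix(sc, ncol = length(object$classes),
         dimnames = list(NULL, object$classes))
}

#' @export
predict.lg_gate2d <- function(object, table, ...) {
  sc <- gate2d_scores(object, table)
  if (length(object$classes) == 2L) {
    off <- if (is.null(object$offset)) 0 else object$offset
    out <- ifelse(sc[, 1] - sc[, 2] > off, object$classes[2],
                  object$classes[1])
  } else {
    out <- object$classes[max.col(-sc, ties.method = "first")]
  }
  out[is.na(sc[, 1])] <- NA_character_
  out
}

#' @export
print.lg_gate2d <- function(x, ...) {
  cat(sprintf("<gate2d> (%s, %s): %s\n", x$fx, x$fy,
              paste(x$classes, collapse = " | ")))
  invisible(x)
}
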