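# Biological classification of track lineages: de-clustering program calls,
# dot identities, anaphase segregation ratios, and goodness of fit against
# the random-segregation null.

#' Classify the centromere de-clustering program of a cell
#'
#' Operates on a track lineage rooted at (at most) the three-dot stage
#' {Aa, Ab, XY4}. The most intense initial track is labeled XY4. Splits of
#' the two other initial dots must partition intensity approximately 1:1
#' (ratio within `one_to_one_tol`); the first such split defines Aa (into
#' Aa1 + Aa2), the second Ab. Splits of the XY4 lineage are releases; a
#' released product is expected to be about twofold more intense than an
#' Aa1-class dot (within `release_tol` when an intensity scale is
#' available). The timing of the first XY4 release relative to the two
#' autosomal splits selects the program: after both -> `canonical`;
#' between them -> `variant_four_dot`; before both -> `variant_three_dot`.
#' Lineages violating these rules (or without events) are labeled `other`.
#'
#' @param tracks A `tracks` data frame with `intensity`.
#' @param events Split events from [detect_splits_fusions()] (fusions are
#'   ignored; ambiguous events make the call `other`).
#' @param one_to_one_tol Ratio bracket for "approximately 1:1" split
#'   products (default `c(0.67, 1.5)`).
#' @param release_tol Bracket for released-dot intensity as a multiple of
#'   the Aa1-class intensity (default `c(1.6, 2.4)`, around the expected
#'   twofold).
#' @return A `decluster_call`: list with `program`, `identities` (named by
#'   track id), `splits` (annotated event table), `notes`.
#' @export
classify_decluster_program <- function(tracks, events,
                                       one_to_one_tol = c(0.67, 1.5),
                                       release_tol = c(1.6, 2.4)) {
  if (!"intensity" %in% names(tracks) || all(is.na(tracks$intensity)))
    stop("track intensities are required for program classification")
  t0 <- min(tracks$frame)
  roots <- unique(tracks$track[tracks$frame == t0])
  if (length(roots) > 3L)
    stop("lineage must be rooted at <= 3 initial dots (three-dot stage)")
  call_other <- function(note) {
    structure(list(program = "other", identities = character(),
                   splits = events, notes = note),
              class = "decluster_call")
  }
  sp <- events[events$kind == "split", , drop = FALSE]
  if (any(sp$ambiguous)) return(call_other("ambiguous split association"))
  if (nrow(sp) == 0L) return(call_other("no events"))
  sp <- sp[order(sp$frame), , drop = FALSE]

  med_int <- vapply(split(tracks$intensity, tracks$track),
                    stats::median, numeric(1), na.rm = TRUE)
  root_int <- med_int[as.character(roots)]
  xy4_root <- roots[which.max(root_int)]

  # membership of each track in an initial lineage: follow child2 -> parent
  lineage_of <- stats::setNames(roots, as.character(roots))
  for (i in seq_len(nrow(sp))) {
    par_lin <- lineage_of[as.character(sp$parent[i])]
    if (is.na(par_lin)) next
    lineage_of[as.character(sp$child2[i])] <- par_lin
  }

  # median track intensity over a short window after `frame`, truncated
  # before the track next acts as a split parent. The median over a few
  # frames is robust to the transient cross-contamination of freshly
  # separated dots, while the short window guards against intensity steps
  # from later (possibly uncalled) splits of the same track.
  seg_median <- function(id, frame, window = 3L) {
    later <- sp$frame[sp$parent == id & sp$frame > frame]
    hi <- min(if (length(later)) min(later) - 1L else Inf,
              frame + window - 1L)
    tr <- tracks[tracks$track == id & tracks$frame >= frame &
                   tracks$frame <= hi, , drop = FALSE]
    if (!nrow(tr)) return(NA_real_)
    stats::median(tr$intensity, na.rm = TRUE)
  }

  sp$lineage <- lineage_of[as.character(sp$parent)]
  notes <- character()
  if (any(is.na(sp$lineage))) {
    # a parent track whose own origin event was not called descends from
    # some already-split lineage; such late splits carry no information
    # about the program ordering and are dropped from the inference
    notes <- c(notes, sprintf("%d split(s) with unassigned lineage ignored",
                              sum(is.na(sp$lineage))))
    sp <- sp[!is.na(sp$lineage), , drop = FALSE]
    if (nrow(sp) == 0L) return(call_other("no events with known lineage"))
  }
  if (any(is.na(sp$partition_fraction)))
    return(call_other("split without intensity partition"))
  sp$is_release <- sp$lineage == xy4_root
  auto <- sp[!sp$is_release, , drop = FALSE]
  rel <- sp[sp$is_release, , drop = FALSE]

  # only splits of the two autosomal root lineages count as Aa/Ab splits;
  # each must be ~1:1
  if (nrow(auto) > 2L) return(call_other("more than two autosomal splits"))
  if (nrow(auto)) {
    ratio <- vapply(seq_len(nrow(auto)), function(i)
      seg_median(auto$child1[i], auto$frame[i]) /
        seg_median(auto$child2[i], auto$frame[i]), numeric(1))
    if (any(is.na(ratio)) ||
        any(ratio < one_to_one_tol[1] | ratio > one_to_one_tol[2]))
      return(call_other("autosomal split not ~1:1"))
  }

  identities <- stats::setNames(character(0), character(0))
  identities[as.character(xy4_root)] <- "XY4"
  aa1_scale <- NA_real_
  if (nrow(auto) >= 1L) {
    aa <- auto[1, ]
    # the continuing track is Aa before the split and Aa1 after; the
    # post-split label wins in the flat map
    identities[as.character(aa$parent)] <- "Aa"
    identities[as.character(aa$child1)] <- "Aa1"
    identities[as.character(aa$child2)] <- "Aa2"
    aa1_scale <- mean(c(seg_median(aa$child1, aa$frame),
                        seg_median(aa$child2, aa$frame)), na.rm = TRUE)
  }
  if (nrow(auto) >= 2L) {
    ab <- auto[2, ]
    identities[as.character(ab$parent)] <- "Ab"
    identities[as.character(ab$child1)] <- "Ab1"
    identities[as.character(ab$child2)] <- "Ab2"
  }
  # the remaining autosomal root (never split) keeps its cluster label
  other_roots <- setdiff(as.character(roots), names(identities))
  for (orr in other_roots)
    identities[orr] <- if (nrow(auto) >= 1L) "Ab" else "Aa_or_Ab"

  if (nrow(rel)) {
    # of the two release products, the released dot is the less intense one
    # (the remainder of the most intense cluster continues as XY4)
    rel1 <- rel[1, ]
    rel_int <- min(seg_median(rel1$child1, rel1$frame),
                   seg_median(rel1$child2, rel1$frame), na.rm = TRUE)
    if (!is.na(aa1_scale) && is.finite(rel_int)) {
      mult <- rel_int / aa1_scale
      if (mult < release_tol[1] || mult > release_tol[2])
        return(call_other(sprintf(
          "released dot intensity %.2fx Aa1, outside the ~2x bracket", mult)))
    }
    identities[as.character(rel1$child2)] <- "released-Y-or-4"
  }

  program <- if (nrow(rel) == 0L) {
    "canonical"
  } else {
    frel <- rel$frame[1]
    n_auto_before <- sum(auto$frame <= frel)
    if (n_auto_before >= 2L) "canonical"
    else if (n_auto_before == 1L) "variant_four_dot"
    else "variant_three_dot"
  }
  structure(list(program = program, identities = identities, splits = sp,
                 notes = if (length(notes)) notes else NULL),
            class = "decluster_call")
}

#' @export
print.decluster_call <- function(x, ...) {
  cat("de-clustering program:", x$program, "\n")
  if (length(x$identities)) {
    cat("identities:\n")
    for (id in names(x$identities))
      cat("  track", id, "->", x$identities[[id]], "\n")
  }
  if (!is.null(x$notes)) cat("notes:", x$notes, "\n")
  invisible(x)
}

#' Classify anaphase segregation ratio
#'
#' Assigns each scored unit to the nearer of two poles and reports the
#' unordered pole ratio a:b (a >= b). Poles are either supplied as two
#' anchor positions or inferred as the two most extreme clusters along the
#' principal axis of the final-frame positions (1D 2-means initialized at
#' the extremes, which is deterministic). Units equidistant from both
#' poles within `tie_tol` are flagged unresolved and excluded with a
#' warning.
#'
#' @param positions Data frame with `x`, `y`, `z` (one row per scored
#'   unit, final frame) and optionally `id`.
#' @param poles Optional 2 x 3 matrix of pole anchor positions.
#' @param tie_tol Micrometers; tie tolerance (localization-noise scale).
#' @return A `segregation_call`: list with `ratio` (e.g. `"5:3"`), `a`,
#'   `b`, `equal_split`, `assignment` (pole 1/2 per unit, NA when
#'   unresolved), `n_unresolved`.
#' @export
classify_segregation <- function(positions, poles = NULL, tie_tol = 0.05) {
  P <- as.matrix(positions[, c("x", "y", "z")])
  if (is.null(poles)) {
    ctr <- colMeans(P)
    pc <- prcomp(P, center = TRUE, scale. = FALSE)
    proj <- as.numeric(scale(P, center = ctr, scale = FALSE) %*%
                         pc$rotation[, 1])
    # 1D 2-means initialized at the extremes (deterministic)
    c1 <- min(proj); c2 <- max(proj)
    for (it in 1:100) {
      g <- ifelse(abs(proj - c1) <= abs(proj - c2), 1L, 2L)
      n1 <- mean(proj[g == 1L]); n2 <- mean(proj[g == 2L])
      if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
      c1 <- n1; c2 <- n2
    }
    poles <- rbind(ctr + c1 * pc$rotation[, 1], ctr + c2 * pc$rotation[, 1])
  }
  d1 <- sqrt(rowSums((P - matrix(poles[1, ], nrow(P), 3, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((P - matrix(poles[2, ], nrow(P), 3, byrow = TRUE))^2))
  assignment <- ifelse(d1 < d2, 1L, 2L)
  tie <- abs(d1 - d2) <= tie_tol
  if (any(tie)) {
    warning(sum(tie), " unit(s) equidistant from both poles; excluded")
    assignment[tie] <- NA_integer_
  }
  n1 <- sum(assignment == 1L, na.rm = TRUE)
  n2 <- sum(assignment == 2L, na.rm = TRUE)
  a <- max(n1, n2); b <- min(n1, n2)
  structure(list(ratio = paste0(a, ":", b), a = a, b = b,
                 equal_split = a == b, assignment = assignment,
                 n_unresolved = sum(tie)),
            class = "segregation_call")
}

#' @export
print.segregation_call <- function(x, ...) {
  cat("segregation ratio:", x$ratio,
      if (x$equal_split) "(equal split)" else "", "\n")
  invisible(x)
}

#' Goodness of fit of observed segregation ratios against a null
#'
#' Pearson chi-square statistic plus a seeded Monte-Carlo estimate of the
#' exact multinomial p value (the probability, under the null, of a table
#' at most as likely as the observed one).
#'
#' @param observed Named integer vector of counts per ratio class (names
#'   must match the null's classes, e.g. `"5:3"`).
#' @param null Data frame from [random_segregation_null()].
#' @param n_sim Number of Monte-Carlo tables.
#' @param seed Integer seed.
#' @return List: `chi_square`, `df`, `p_value`, `table` (class, expected,
#'   observed).
#' @export
null_comparison <- function(observed, null, n_sim = 10000L, seed = 1L) {
  if (!setequal(names(observed), null$class))
    stop("observed classes do not match null classes")
  obs <- as.numeric(observed[null$class])
  n <- sum(obs)
  p <- null$probability
  expd <- n * p
  nz <- expd > 0
  chi <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  if (any(!nz) && any(obs[!nz] > 0)) chi <- Inf
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  logp_obs <- stats::dmultinom(obs, prob = p, log = TRUE)
  sims <- stats::rmultinom(n_sim, n, p)
  logp_sim <- apply(sims, 2, stats::dmultinom, prob = p, log = TRUE)
  pval <- mean(logp_sim <= logp_obs + 1e-9)
  list(chi_square = chi, df = sum(nz) - 1L, p_value = pval,
       table = data.frame(class = null$class, expected = expd,
                          observed = obs))
}
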