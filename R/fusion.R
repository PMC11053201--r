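#' Linear weighted fusion of video and audio probabilities
#'
#' Combines per-clip fall probabilities from the two modalities as
#' `c = alpha * a + (1 - alpha) * b`, where `a` is the video probability and
#' `b` the audio probability. `alpha` is the weight of the video modality;
#' because audio is meant as a supplement to video, weights in `[0.6, 0.9]`
#' are the intended operating range and values outside it trigger a warning
#' (not an error).
#'
#' @param a,b Numeric vectors of probabilities in `[0, 1]` (video, audio).
#' @param alpha Video-modality weight in `[0, 1]`.
#' @return Fused probabilities, same length as `a`.
#' @examples
#' linear_fuse(0.9, 0.5, alpha = 0.7) # 0.78
#' @export
linear_fuse <- function(a, b, alpha = 0.7) {
  check_prob(a, "a")
  check_prob(b, "b")
  check_prob(alpha, "alpha")
  if (length(alpha) != 1L) stop("`alpha` must be a single weight")
  if (alpha < 0.6 || alpha > 0.9) {
    warning("alpha = ", alpha, " lies outside the intended video-weight range [0.6, 0.9]")
  }
  alpha * a + (1 - alpha) * b
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop("`", name, "` must be numeric in [0, 1]")
  }
  invisible(x)
}

#' Basic probability assignment over the fall/not-fall frame
#'
#' Builds a Dempster-Shafer mass function on the frame of discernment
#' `{fall, notfall}` from a classifier's fall probability. A `discount`
#' fraction of the unit mass is withheld from the singletons and assigned to
#' the whole frame (total ignorance), modelling limited trust in the source:
#' `m({fall}) = (1-discount)*p`, `m({notfall}) = (1-discount)*(1-p)`,
#' `m(frame) = discount`. The empty set always carries mass 0.
#'
#' @param p_fall Fall probability in `[0, 1]`.
#' @param discount Source discount in `[0, 1]`; `0` (default) trusts the
#'   probability fully.
#' @return A `mass_function`: named numeric `c(fall=, notfall=, theta=)`
#'   summing to 1.
#' @examples
#' mass_from_probability(0.8, discount = 0.1)
#' @export
mass_from_probability <- function(p_fall, discount = 0) {
  check_prob(p_fall, "p_fall")
  check_prob(discount, "discount")
  stopifnot(length(p_fall) == 1L, length(discount) == 1L)
  mass_function(fall = (1 - discount) * p_fall,
                notfall = (1 - discount) * (1 - p_fall),
                theta = discount)
}

#' Construct a mass function on {fall, notfall}
#'
#' @param fall,notfall,theta Masses for the two singleton hypotheses and the
#'   whole frame; must be in `[0, 1]` and sum to 1 (tolerance 1e-9).
#' @return A `mass_function` object.
#' @export
mass_function <- function(fall, notfall, theta = 0) {
  m <- c(fall = fall, notfall = notfall, theta = theta)
  check_prob(unname(m), "masses")
  if (abs(sum(m) - 1) > 1e-9) {
    stop("mass function must sum to 1 (got ", format(sum(m)), ")")
  }
  structure(m, class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat(sprintf("m({fall}) = %.4f  m({notfall}) = %.4f  m(Theta) = %.4f\n",
              x[["fall"]], x[["notfall"]], x[["theta"]]))
  invisible(x)
}

#' Dempster's rule of combination
#'
#' Conjunctively combines two mass functions over `{fall, notfall}`. For each
#' non-empty hypothesis A, `m(A) = sum over B∩C=A of m1(B)·m2(C) / (1-K)`,
#' where the conflict `K = sum over B∩C=∅ of m1(B)·m2(C)` collects the mass of
#' contradictory pairs. Total conflict (`K = 1`) is an explicit error: the two
#' sources flatly contradict each other and no renormalized combination
#' exists.
#'
#' @param m1,m2 `mass_function` objects (video and audio evidence).
#' @return The combined `mass_function`, with the conflict attached as
#'   attribute `"conflict"`.
#' @examples
#' m1 <- mass_function(0.8, 0.2)
#' m2 <- mass_function(0.6, 0.4)
#' dempster_combine(m1, m2) # K = 0.44, m({fall}) ~ 0.857
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  # On a two-hypothesis frame the only empty intersections are the
  # singleton-vs-opposite-singleton pairs.
  K <- m1[["fall"]] * m2[["notfall"]] + m1[["notfall"]] * m2[["fall"]]
  if (K >= 1 - 1e-12) {
    stop("total conflict between sources (K = 1): combination undefined")
  }
  fall <- m1[["fall"]] * m2[["fall"]] +
    m1[["fall"]] * m2[["theta"]] + m1[["theta"]] * m2[["fall"]]
  notfall <- m1[["notfall"]] * m2[["notfall"]] +
    m1[["notfall"]] * m2[["theta"]] + m1[["theta"]] * m2[["notfall"]]
  theta <- m1[["theta"]] * m2[["theta"]]
  out <- mass_function(fall / (1 - K), notfall / (1 - K), theta / (1 - K))
  attr(out, "conflict") <- K
  out
}

#' Belief and plausibility of a hypothesis
#'
#' `bel(A)` sums the mass of all subsets of A; `pl(A)` sums the mass of all
#' hypotheses intersecting A. The interval `[bel, pl]` is the credibility
#' interval of A, with `bel(A) <= pl(A)` and `pl(A) = 1 - bel(complement(A))`.
#'
#' @param m A `mass_function`.
#' @param hypothesis One of `"fall"`, `"notfall"`, `"theta"` (the whole frame).
#' @return Named numeric `c(bel=, pl=)`.
#' @export
belief_plausibility <- function(m, hypothesis = c("fall", "notfall", "theta")) {
  stopifnot(inherits(m, "mass_function"))
  hypothesis <- match.arg(hypothesis)
  switch(hypothesis,
    fall = c(bel = unname(m[["fall"]]),
             pl = unname(m[["fall"]] + m[["theta"]])),
    notfall = c(bel = unname(m[["notfall"]]),
                pl = unname(m[["notfall"]] + m[["theta"]])),
    theta = c(bel = 1, pl = 1)
  )
}

#' Threshold a fused score or mass into a label
#'
#' The linear-weighting path thresholds the fused probability directly. The
#' Dempster-Shafer path defaults to the pignistic probability, which splits
#' the mass on the whole frame equally between the singletons:
#' `BetP(fall) = m({fall}) + m(Theta)/2`; the `"belief"` rule uses `bel({fall})`
#' instead. Ties at exactly the threshold are classified `"notfall"`
#' (conservative for specificity).
#'
#' @param x A fused probability in `[0, 1]` or a `mass_function`.
#' @param threshold Decision threshold, default 0.5.
#' @param rule For mass functions: `"pignistic"` (default) or `"belief"`.
#' @return `"fall"` or `"notfall"`.
#' @export
decide <- function(x, threshold = 0.5, rule = c("pignistic", "belief", "probability")) {
  rule <- match.arg(rule)
  score <- if (inherits(x, "mass_function")) {
    if (rule == "belief") unname(x[["fall"]]) else unname(x[["fall"]] + x[["theta"]] / 2)
  } else {
    check_prob(x, "x")
    x
  }
  ifelse(score > threshold, "fall", "notfall")
}

#' Fuse two per-clip score tables
#'
#' Joins video and audio score tables on `clip_id` and fuses each pair by the
#' requested method, returning labels and fused scores.
#'
#' @param video,audio Data frames with columns `clip_id` and `prob` (fall
#'   probability).
#' @param method `"linear"` or `"dempster"`.
#' @param alpha Video weight for linear fusion.
#' @param discount Source discount applied to both modalities before Dempster
#'   combination.
#' @param threshold Decision threshold.
#' @return Data frame `clip_id, video_prob, audio_prob, fused, label` (plus
#'   `conflict` for the Dempster method).
#' @export
fuse_scores <- function(video, audio, method = c("linear", "dempster"),
                        alpha = 0.7, discount = 0, threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(all(c("clip_id", "prob") %in% names(video)),
            all(c("clip_id", "prob") %in% names(audio)))
  merged <- merge(video[, c("clip_id", "prob")], audio[, c("clip_id", "prob")],
                  by = "clip_id", suffixes = c("_video", "_audio"))
  if (nrow(merged) == 0) stop("no clip_id overlap between modalities")
  a <- merged$prob_video
  b <- merged$prob_audio
  if (method == "linear") {
    fused <- linear_fuse(a, b, alpha)
    data.frame(clip_id = merged$clip_id, video_prob = a, audio_prob = b,
               fused = fused, label = decide(fused, threshold))
  } else {
    res <- lapply(seq_along(a), function(i) {
      m <- dempster_combine(mass_from_probability(a[i], discount),
                            mass_from_probability(b[i], discount))
      c(fused = unname(m[["fall"]] + m[["theta"]] / 2),
        conflict = attr(m, "conflict"))
    })
    fused <- vapply(res, `[[`, numeric(1), "fused")
    data.frame(clip_id = merged$clip_id, video_prob = a, audio_prob = b,
               fused = fused, conflict = vapply(res, `[[`, numeric(1), "conflict"),
               label = decide(fused, threshold))
  }
}
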