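#' Feedback-loop parameters
#'
#' @param gamma_th Happiness threshold in (0, 1) separating the positive
#'   (micro-affirmation) from the negative (micro-inequity) feedback branch.
#' @param n_rounds_per_epoch Monte Carlo sweeps per epoch (`N_r`).
#' @param n_feedback_rounds Number of feedback rounds after the baseline
#'   epoch (default 4).
#' @param gamma_mode `"behavioral"`: the happiness index is the fraction of
#'   cooperative rounds. `"blended"`: it is averaged with the node's min-max
#'   normalized biomass + ATP-synthase flux sum, letting the gut fluxes
#'   co-determine happiness.
#' @return Object of class `feedback_params`.
#' @export
feedback_params <- function(gamma_th = 0.5, n_rounds_per_epoch = 100,
                            n_feedback_rounds = 4,
                            gamma_mode = c("behavioral", "blended")) {
  if (gamma_th <= 0 || gamma_th >= 1)
    stop("gamma_th must be in (0,1)", call. = FALSE)
  if (n_rounds_per_epoch < 1) stop("n_rounds_per_epoch >= 1", call. = FALSE)
  structure(list(gamma_th = gamma_th,
                 n_rounds_per_epoch = as.integer(n_rounds_per_epoch),
                 n_feedback_rounds = as.integer(n_feedback_rounds),
                 gamma_mode = match.arg(gamma_mode)),
            class = "feedback_params")
}

#' Happiness index of a node
#'
#' Fraction of epoch rounds in which the node cooperated:
#' `gamma = (# cooperative rounds) / N_r`, in `[0, 1]`. 1 means fully
#' cooperative with a proactive attitude, 0 a complete lack of
#' cooperativeness.
#'
#' @param coop_history 0/1 vector (or rounds x nodes matrix) of per-round
#'   cooperation indicators for the epoch.
#' @param n_rounds Number of rounds `N_r`; defaults to the history length.
#' @return Scalar (or per-node vector) in `[0, 1]`.
#' @export
happiness_index <- function(coop_history, n_rounds = NULL) {
  if (is.matrix(coop_history)) {
    if (nrow(coop_history) == 0) stop("empty history", call. = FALSE)
    n_rounds <- n_rounds %||% nrow(coop_history)
    return(colSums(coop_history) / n_rounds)
  }
  if (length(coop_history) == 0) stop("empty history", call. = FALSE)
  n_rounds <- n_rounds %||% length(coop_history)
  sum(coop_history) / n_rounds
}

#' Gut bias
#'
#' Per-round rate of accumulation of the branch-relevant counter:
#' `epsilon = (sum MA) / N_r` under a positive sign, `(sum MI) / N_r` under a
#' negative one. Vectorized.
#'
#' @param ma_total,mi_total Epoch counter totals (>= 0).
#' @param sign `"positive"`/`"negative"` (or logical: positive?).
#' @param n_rounds Rounds per epoch `N_r`.
#' @return Nonnegative scalar/vector.
#' @export
gut_bias <- function(ma_total, mi_total, sign, n_rounds) {
  pos <- if (is.character(sign)) sign == "positive" else as.logical(sign)
  ifelse(pos, ma_total, mi_total) / n_rounds
}

#' Per-node feedback outcome
#'
#' Computes the happiness index, the branch sign (`gamma >= gamma_th` is
#' positive) and the gut bias for every node.
#'
#' @param gamma Per-node happiness indices.
#' @param ma,mi Per-node epoch counter totals.
#' @param params A [feedback_params()].
#' @param flux_score Optional per-node biomass + ATP-synthase flux sums; with
#'   `gamma_mode = "blended"` their min-max normalization is averaged into
#'   `gamma` before thresholding.
#' @return Object of class `feedback_outcome`: list with `gamma`, `sign`,
#'   `epsilon`.
#' @export
feedback_outcome <- function(gamma, ma, mi, params, flux_score = NULL) {
  if (params$gamma_mode == "blended" && !is.null(flux_score)) {
    rng <- range(flux_score)
    norm <- if (diff(rng) > 0) (flux_score - rng[1]) / diff(rng)
            else rep(0.5, length(flux_score))
    gamma <- (gamma + norm) / 2
  }
  sign <- ifelse(gamma >= params$gamma_th, "positive", "negative")
  structure(list(gamma = gamma, sign = sign,
                 epsilon = gut_bias(ma, mi, sign,
                                    params$n_rounds_per_epoch)),
            class = "feedback_outcome")
}

#' Amplify MA/MI counters by the gut bias
#'
#' Positive nodes: `MA <- MA * (1 + epsilon)`; negative nodes:
#' `MI <- MI * (1 + epsilon)`. The amplified counters are carried into the
#' next epoch's psi estimator. Amplification never decreases a counter.
#'
#' @param outcome A [feedback_outcome()].
#' @param ma,mi Per-node counters.
#' @return List with amplified `ma` and `mi`.
#' @export
apply_gut_feedback <- function(outcome, ma, mi) {
  pos <- outcome$sign == "positive"
  ma[pos] <- ma[pos] * (1 + outcome$epsilon[pos])
  mi[!pos] <- mi[!pos] * (1 + outcome$epsilon[!pos])
  list(ma = ma, mi = mi)
}

#' Diet-perturbation limits
#'
#' Half-width and limits of the perturbation interval of one macronutrient
#' percentage: `w = (1 - gamma) * 10` percentage points, limits
#' `[p - w, p + w]` (clamped to `[0, 100]` only where they leave the valid
#' range). A fully happy node (`gamma = 1`) keeps its diet unchanged.
#'
#' @param pct Current percentage.
#' @param gamma Happiness index in `[0, 1]`.
#' @return List with `halfwidth`, `lower`, `upper`.
#' @examples
#' diet_perturbation_limits(50, 0.0800586)  # halfwidth 9.19941
#' @export
diet_perturbation_limits <- function(pct, gamma) {
  if (any(gamma < 0 | gamma > 1)) stop("gamma must be in [0,1]", call. = FALSE)
  w <- (1 - gamma) * 10
  list(halfwidth = w,
       lower = pmax(0, pct - w),
       upper = pmin(100, pct + w))
}

#' Randomly perturb a diet under the happiness index
#'
#' Each macronutrient percentage may move by at most `(1 - gamma) * 10`
#' percentage points: new integer percentages are drawn uniformly inside the
#' per-nutrient limits until the three sum to exactly 100 (carbohydrate and
#' fat drawn, protein set to the remainder and accepted iff inside its own
#' limits; after `max_tries` rejections the feasible integer pairs are
#' enumerated directly, and if none exists all limits are widened by one
#' point with a warning).
#'
#' @param diet A [diet_spec()].
#' @param gamma Happiness index in `[0, 1]`.
#' @param max_tries Rejection-sampling budget before enumeration.
#' @return A new [diet_spec()] with the same sugar fraction and basal rates.
#' @export
perturb_diet <- function(diet, gamma, max_tries = 1000) {
  p <- c(diet$carb_pct, diet$fat_pct, diet$protein_pct)
  if (gamma >= 1) return(diet)
  lim <- diet_perturbation_limits(p, gamma)
  lo <- ceiling(lim$lower - 1e-9); hi <- floor(lim$upper + 1e-9)
  runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  draw <- function(lo, hi) {
    for (t in seq_len(max_tries)) {
      carb <- runif_int(lo[1], hi[1])
      fat <- runif_int(lo[2], hi[2])
      prot <- 100L - carb - fat
      if (prot >= lo[3] && prot <= hi[3])
        return(c(carb, fat, prot))
    }
    grid <- expand.grid(carb = lo[1]:hi[1], fat = lo[2]:hi[2])
    grid$prot <- 100L - grid$carb - grid$fat
    ok <- grid$prot >= lo[3] & grid$prot <= hi[3]
    if (any(ok)) {
      pick <- grid[ok, , drop = FALSE][sample(sum(ok), 1), ]
      return(c(pick$carb, pick$fat, pick$prot))
    }
    NULL
  }
  q <- draw(lo, hi)
  while (is.null(q)) {
    warning("perturbation limits admit no integer simplex point; widening by 1")
    lo <- pmax(0, lo - 1L); hi <- pmin(100, hi + 1L)
    q <- draw(lo, hi)
  }
  diet_spec(q[1], q[2], q[3], sugar_fraction = diet$sugar_fraction,
            basal_rates = diet$basal_rates)
}
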