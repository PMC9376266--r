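#' Learning-behavior configuration
#'
#' Bundles the enable flags and thresholds for the three cognitive
#' learning behaviors layered on top of basic Hebbian association.
#' Thresholds are given in multiples of `v_ON` (the field idiom, e.g.
#' "6 v_ON") and converted to absolute values inside the simulator.
#'
#' @param predictive Enable the predictive behavior.
#' @param p_th_von Prediction threshold, in multiples of `v_ON`: a
#'   non-input neuron whose feedback reaches this level during an
#'   association joins the memory being stored (default 6).
#' @param erase Enable the erase (consolidation) behavior.
#' @param r_th_von Erase threshold, in multiples of `v_ON`: a neuron whose
#'   incoming weights sum to this level has all its synapses reset
#'   (default 400).
#' @param forgetting Enable passive synaptic decay.
#' @param d_rate Per-time-step decay fraction in `[0, 1)`; the degenerate
#'   value 1 ("forget everything each step") is accepted for diagnostic
#'   runs (default 0.015).
#' @return An object of class `san_behaviors`.
#' @export
behavior_config <- function(predictive = FALSE, p_th_von = 6,
                            erase = FALSE, r_th_von = 400,
                            forgetting = FALSE, d_rate = 0.015) {
  if (predictive && p_th_von <= 0) stop("p_th_von must be positive")
  if (erase && r_th_von <= 0) stop("r_th_von must be positive")
  if (d_rate < 0 || d_rate > 1) stop("d_rate must be in [0, 1]")
  structure(
    list(predictive = isTRUE(predictive), p_th_von = p_th_von,
         erase = isTRUE(erase), r_th_von = r_th_von,
         forgetting = isTRUE(forgetting), d_rate = d_rate),
    class = "san_behaviors"
  )
}

#' Predictive behavior: associate high-feedback bystanders
#'
#' During the association of `memory` (with external input clamped on all
#' of its features), any neuron *not* receiving external input whose
#' output — equal to its recurrent feedback, since its own `E` is zero —
#' reaches the threshold `p_th` associates itself with every clamped
#' feature of the memory in both directions (cross-set only, at `v_ON`).
#' The sweep is single and non-cascading: freshly created weights cannot
#' push further neurons over threshold within the same association.
#'
#' @param net A [san_network] in which `memory` has just been associated.
#' @param memory Integer feature-index vector of length `n`.
#' @param p_th Absolute threshold (e.g. `6 * net$v_on`).
#' @return List with `net` (updated network), `predicted` (global indices
#'   of triggered neurons), and `n_predictions`.
#' @export
apply_predictive <- function(net, memory, p_th) {
  stopifnot(inherits(net, "san_network"), p_th > 0)
  memory <- .check_memory(net$schema, memory)
  glob <- memory_neurons(net$schema, memory)
  E <- numeric(net$N)
  E[glob] <- net$e_mag
  f <- .san_outputs(net$W, E)
  trig <- which(E == 0 & f >= p_th)
  for (p in trig) {
    others <- glob[net$set_id[glob] != net$set_id[p]]  # clamped, cross-set
    net$W[p, others] <- net$v_on
    net$W[others, p] <- net$v_on
  }
  list(net = net, predicted = trig, n_predictions = length(trig))
}

#' Erase behavior: reset commonly recurring features
#'
#' A neuron whose incoming (pre-synaptic) weight sum reaches `r_th` is
#' deemed a commonly recurring feature and has *all* of its pre- and
#' post-synaptic weights reset to zero. All neurons are judged against a
#' snapshot of the sums taken before any zeroing, so erasing one neuron
#' cannot rescue another in the same sweep. The reset is not pruning: the
#' connections can be re-programmed later.
#'
#' @param net A [san_network].
#' @param r_th Absolute threshold (e.g. `400 * net$v_on`).
#' @return List with `net`, `erased` (global indices of reset neurons,
#'   possibly empty), and `pre_sums` (their snapshot incoming sums).
#' @export
apply_erase <- function(net, r_th) {
  stopifnot(inherits(net, "san_network"), r_th > 0)
  pre <- .colSums(net$W, net$N, net$N)   # incoming sum per neuron, snapshot
  erased <- which(pre >= r_th)
  if (length(erased)) {
    net$W[erased, ] <- 0
    net$W[, erased] <- 0
  }
  list(net = net, erased = erased, pre_sums = pre[erased])
}

#' Forgetting behavior: uniform synaptic decay
#'
#' Multiplies every weight by `(1 - d_rate)`, the discrete-time decay
#' applied once per simulation step. Zero weights stay zero; `t` repeated
#' applications give `v_ON * (1 - d_rate)^t` exactly (up to floating
#' error). Re-association restores a decayed weight to full `v_ON`.
#'
#' @param net A [san_network].
#' @param d_rate Decay fraction in `[0, 1)`; 1 is accepted as the
#'   degenerate "forget everything each step" limit.
#' @return The decayed network.
#' @export
apply_forgetting <- function(net, d_rate) {
  stopifnot(inherits(net, "san_network"))
  if (d_rate < 0 || d_rate > 1) stop("d_rate must be in [0, 1]")
  if (d_rate > 0) net$W <- net$W * (1 - d_rate)
  net
}

#' Size the erase threshold from a known similarity frequency
#'
#' If a feature is known to occur in a fraction `f_sim` of the `I_tot`
#' memories, setting `R_th = I_tot * f_sim * v_ON` erases it exactly when
#' all of its occurrences have been stored. The value is returned as the
#' coefficient of `v_ON` (multiply by `v_ON` for the absolute threshold).
#'
#' @param i_tot Number of memories in the dataset (>= 1).
#' @param f_sim Similarity frequency in `(0, 1]`.
#' @return `R_th` in multiples of `v_ON`.
#' @examples
#' erase_threshold_from_similarity(100, 0.6)  # 60
#' @export
erase_threshold_from_similarity <- function(i_tot, f_sim) {
  if (i_tot < 1) stop("i_tot must be >= 1")
  if (f_sim <= 0 || f_sim > 1) stop("f_sim must be in (0, 1]")
  if (round(f_sim * i_tot) < 1)
    stop("f_sim corresponds to fewer than one occurrence")
  i_tot * f_sim
}
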