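#' @rdname build_network
#' @format NULL
#' @export
VARIANTS <- c("control", "IPSC", "IPSC+gGABA", "IPSC+bInh", "Full")

#' Build the control network or a schizophrenia-like variant
#'
#' Constructs the all-to-all microcircuit of `n_E` pyramidal cells, `n_I`
#' inhibitory interneurons and one pacemaker drive cell. Synapses from
#' excitatory cells (and the pacemaker) carry sign +1 and decay time
#' `tau_exc`; synapses from inhibitory cells carry sign -1 and the
#' inhibitory decay time. The variants implement the three
#' schizophrenia-associated alterations:
#'
#' * `"control"` - published defaults verbatim (`tau_inh` = 8 ms, applied
#'   current b for all cells).
#' * `"IPSC"` - prolonged GABAergic IPSC decay: `tau_inh` raised to
#'   `tau_inh_scz` (28 ms) on inhibitory synapses.
#' * `"IPSC+gGABA"` - additionally reduced GABA levels: `g_ie` and `g_ii`
#'   multiplied by `gGABA_level`.
#' * `"IPSC+bInh"` - additionally NMDAR hypofunction: the applied current of
#'   inhibitory cells lowered to `-bInh_level` (so `bInh_level = 0.01`
#'   equals the control current and larger magnitudes are stronger
#'   hypofunction).
#' * `"Full"` - all three alterations.
#'
#' The swept interneuron-excitability values are interpreted as the
#' absolute magnitude of the (negative) inhibitory applied current, whose
#' mildest published setting (0.01) coincides with the control current; set
#' `bInh_as_decrement = TRUE` to instead subtract `bInh_level` from the
#' control current.
#'
#' Internally, synapses sharing a presynaptic cell and a decay time are
#' grouped: their gating variables obey the same ODE, so one state per group
#' is integrated and fanned out through the signed weight matrix.
#'
#' @param variant one of `VARIANTS`.
#' @param params a [model_parameters()] object.
#' @param gGABA_level GABA weight scaling in (0, 1]; ignored unless the
#'   variant includes the gGABA alteration.
#' @param bInh_level magnitude of the reduced inhibitory applied current
#'   (0 = leave at control); ignored unless the variant includes the bInh
#'   alteration.
#' @param tau_inh_scz prolonged IPSC decay time (ms) of the SCZ variants.
#' @param autapses include self-synapses within a population (default TRUE;
#'   the all-to-all rule is applied without exclusions).
#' @param ipsc_ie_only apply the IPSC decay prolongation only to I->E
#'   synapses instead of all inhibitory synapses (alternative reading,
#'   default FALSE).
#' @param bInh_as_decrement see above.
#' @param include_drive_in_meg count pacemaker->E synapses in the simulated
#'   MEG sum (default FALSE: the MEG reflects the recurrent E->E gating
#'   variables, so an unresponsive network yields near-zero band power).
#' @return An object of class `assr_network`.
#' @examples
#' net <- build_network("IPSC", model_parameters())
#' unique(net$tau_decay[net$sign < 0])  # 28 ms
#' @export
build_network <- function(variant = VARIANTS, params = model_parameters(),
                          gGABA_level = 1, bInh_level = 0,
                          tau_inh_scz = 28,
                          autapses = TRUE, ipsc_ie_only = FALSE,
                          bInh_as_decrement = FALSE,
                          include_drive_in_meg = FALSE) {
  variant <- match.arg(variant)
  stopifnot(gGABA_level > 0, gGABA_level <= 1, bInh_level >= 0)

  has_ipsc  <- variant %in% c("IPSC", "IPSC+gGABA", "IPSC+bInh", "Full")
  has_ggaba <- variant %in% c("IPSC+gGABA", "Full")
  has_binh  <- variant %in% c("IPSC+bInh", "Full")
  if (!has_ggaba) gGABA_level <- 1
  if (!has_binh) bInh_level <- 0

  n_E <- params$n_E; n_I <- params$n_I
  n <- n_E + n_I
  is_E <- c(rep(TRUE, n_E), rep(FALSE, n_I))

  g_ie <- params$g_ie * gGABA_level
  g_ii <- params$g_ii * gGABA_level
  tau_inh_eff <- if (has_ipsc) tau_inh_scz else params$tau_inh

  b_per_cell <- rep(params$b, n)
  b_inh <- params$b - params$b_inh_delta
  if (has_binh && bInh_level > 0)
    b_inh <- if (bInh_as_decrement) params$b - bInh_level else -bInh_level
  b_per_cell[!is_E] <- b_inh

  # one synapse group per (presynaptic cell, decay time)
  pre <- integer(0); tau <- numeric(0); sign <- numeric(0)
  rows <- list()
  add_group <- function(p, td, sg, w_row) {
    pre  <<- c(pre, p); tau <<- c(tau, td); sign <<- c(sign, sg)
    rows[[length(rows) + 1L]] <<- w_row
  }
  for (j in seq_len(n)) {
    if (is_E[j]) {
      w <- ifelse(is_E, params$g_ee, params$g_ei)
      if (!autapses) w[j] <- 0
      add_group(j, params$tau_exc, +1, w)
    } else {
      w <- ifelse(is_E, g_ie, g_ii)
      if (!autapses) w[j] <- 0
      if (ipsc_ie_only && has_ipsc) {
        w_e <- w; w_e[!is_E] <- 0
        w_i <- w; w_i[is_E] <- 0
        add_group(j, tau_inh_scz, -1, w_e)
        add_group(j, params$tau_inh, -1, w_i)
      } else {
        add_group(j, tau_inh_eff, -1, w)
      }
    }
  }
  # pacemaker drive synapses (rescaled from base strengths by scale_input)
  add_group(n + 1L, params$tau_exc, +1,
            params$I_factor * ifelse(is_E, params$g_de, params$g_di))
  W <- do.call(rbind, rows) * sign  # signed weights, groups x cells

  # multiplicity of each group's excitatory synapses onto pyramidal cells,
  # for the simulated MEG sum of excitatory gating variables
  meg_mult <- vapply(seq_along(pre), function(g) {
    if (sign[g] < 0) return(0)
    if (pre[g] == n + 1L && !include_drive_in_meg) return(0)
    sum(W[g, is_E] != 0)
  }, numeric(1))

  structure(list(
    W = W, pre = pre, tau_decay = tau, sign = sign,
    b_per_cell = b_per_cell,
    n_E = n_E, n_I = n_I, n_cells = n, pacemaker = n + 1L,
    meg_mult = meg_mult,
    variant_label = variant,
    gGABA_level = gGABA_level, bInh_level = bInh_level,
    I_factor = params$I_factor,
    autapses = autapses, ipsc_ie_only = ipsc_ie_only,
    bInh_as_decrement = bInh_as_decrement,
    include_drive_in_meg = include_drive_in_meg,
    params = params
  ), class = "assr_network")
}

#' @export
print.assr_network <- function(x, ...) {
  cat(sprintf("ASSR network '%s': %d E + %d I + pacemaker, %d synapse groups\n",
              x$variant_label, x$n_E, x$n_I, nrow(x$W)))
  cat(sprintf("  tau_inh=%g ms, gGABA level=%g, bInh level=%g, I=%g\n",
              max(x$tau_decay[x$sign < 0], -Inf), x$gGABA_level,
              x$bInh_level, x$I_factor))
  invisible(x)
}

#' Scale the drive input strength
#'
#' Sets the pacemaker drive weights to `I_factor * g_de` (onto E cells) and
#' `I_factor * g_di` (onto I cells), leaving every other weight untouched.
#' Scaling is always relative to the base drive strengths, not cumulative.
#'
#' @param network an `assr_network`.
#' @param I_factor input-strength multiplier, > 0.
#' @return The rescaled network.
#' @export
scale_input <- function(network, I_factor) {
  stopifnot(inherits(network, "assr_network"), I_factor > 0)
  g <- which(network$pre == network$pacemaker)
  is_E <- seq_len(network$n_cells) <= network$n_E
  p <- network$params
  network$W[g, is_E]  <- I_factor * p$g_de
  network$W[g, !is_E] <- I_factor * p$g_di
  network$I_factor <- I_factor
  network
}

#' Alteration sweep grids of the combination experiments
#'
#' Returns the (gGABA_level, bInh_level) settings swept for each
#' combined-alteration model family:
#'
#' * `"IPSC+gGABA"`: GABA weights from 100% down to 10% in steps of 5%
#'   (19 levels), no excitability change.
#' * `"IPSC+bInh"`: inhibitory applied-current magnitudes 0.01 to 0.1 in
#'   steps of 0.01, then 0.15 to 0.6 in steps of 0.05 (20 levels; 0.01
#'   equals the control current), full GABA weights.
#' * `"Full"`: GABA weights 100% to 10% in steps of 10%, paired
#'   simultaneously with 10 excitability levels subsampled from the bInh
#'   grid so both alterations strengthen together.
#'
#' @param variant one of `"IPSC+gGABA"`, `"IPSC+bInh"`, `"Full"`.
#' @return A data.frame with columns `gGABA_level`, `bInh_level`.
#' @export
alteration_grid <- function(variant = c("IPSC+gGABA", "IPSC+bInh", "Full")) {
  variant <- match.arg(variant)
  binh_full <- c(seq(0.01, 0.10, by = 0.01), seq(0.15, 0.60, by = 0.05))
  switch(variant,
    "IPSC+gGABA" = data.frame(
      gGABA_level = seq(1.00, 0.10, by = -0.05),
      bInh_level = 0),
    "IPSC+bInh" = data.frame(
      gGABA_level = 1,
      bInh_level = binh_full),
    "Full" = data.frame(
      gGABA_level = seq(1.0, 0.1, by = -0.1),
      bInh_level = binh_full[round(seq(1, 20, length.out = 10))])
  )
}
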