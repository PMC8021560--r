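#' Reverse rate constant from a stability constant
#'
#' Complex dissociation is closed thermodynamically: with forward rate
#' constant `k1` (1/(M d)) and stability constant `K` (1/M), the reverse
#' first-order rate constant is `k_-1 = k1 / K` (1/d).
#'
#' @param k1 forward (formation) rate constant, 1/(M d)
#' @param K stability constant, 1/M
#' @return reverse rate constant, 1/d
#' @export
reverse_rate <- function(k1, K) {
  if (any(K <= 0)) stop("stability constant must be positive", call. = FALSE)
  if (any(k1 <= 0)) stop("forward rate must be positive", call. = FALSE)
  k1 / K
}

#' Net metal-ligand complexation rates
#'
#' One net rate per complex, `rho = k1*[Me][L] - (k1/K)*[MeL]`, in mol/L/d.
#' Only the fully deprotonated EDTA anion acts as the EDTA ligand; VFA
#' ligands are the carboxylate anions, converted from gCOD/L to M with
#' their COD content (64, 112, 160, 208 gCOD/mol for acetate through
#' valerate). Competition between metals for a shared ligand emerges from
#' the shared free-ligand pool.
#'
#' @param state named state vector
#' @param params an `ad_parameters` object (section `complexes`)
#' @return named vector of net formation rates, one per complex
#' @export
complexation_rates <- function(state, params) {
  cx <- params$complexes
  gcod <- c(S_ac = 64, S_pro = 112, S_bu = 160, S_va = 208)
  lig_conv <- ifelse(cx$ligand %in% names(gcod), 1 / gcod[cx$ligand], 1)
  K <- 10^cx$log10_K
  me <- pmax(state[cx$metal], 0)
  lig <- pmax(state[cx$ligand], 0) * lig_conv
  bound <- pmax(state[cx$complex], 0)
  rho <- cx$k1 * me * lig - (cx$k1 / K) * bound
  stats::setNames(rho, cx$complex)
}
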