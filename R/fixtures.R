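#' The seven-species Fmoc-piperidine oscillator network
#'
#' Declarative encoding of the organic-chemistry oscillator built from four
#' reactions among seven species (indices follow the literature numbering):
#' 1 piperidine, 2 Fmoc-piperidine, 3 p-nitrophenyl acetate, 4 phenyl acetate,
#' 5 N-methylpiperidine (held constant by the setup), 6 dibenzofulvene,
#' 7 N-acetyl piperidine.
#'
#' The reactions:
#' \itemize{
#' \item trigger (`k_tr`): N-methylpiperidine-catalyzed Fmoc-piperidine
#'   deprotection, `2 -> 1 + 6`, rate `k_tr * [2] * [5]` (species 5 enters the
#'   rate law with zero net stoichiometry);
#' \item autocatalysis (`k_ac`): piperidine-mediated deprotection,
#'   `1 + 2 -> 2*1 + 6`, rate `k_ac * [1] * [2]`;
#' \item fast inhibition (`k_inh1`): acetylation by p-nitrophenyl acetate,
#'   `1 + 3 -> 7`, rate `k_inh1 * [1] * [3]`;
#' \item slow inhibition (`k_inh2`): acetylation by phenyl acetate,
#'   `1 + 4 -> 7`, rate `k_inh2 * [1] * [4]`.
#' }
#'
#' Rate-constant values are not part of this package's sources: the
#' `"terharmsel2023"` parameter set ships as `NA` placeholders to be filled
#' from the original experimental work, and all tests use the self-contained
#' `"toy_oscillator"` set (see [toy_oscillator()]).
#'
#' @param kappa named numeric vector with entries `k_tr`, `k_ac`, `k_inh1`,
#'   `k_inh2` (units 1/(M * time_unit)); defaults to `NA` placeholders.
#' @param time_unit time unit of the rate constants.
#' @return a [crn_network()].
#' @export
fmoc_network <- function(kappa = c(k_tr = NA_real_, k_ac = NA_real_,
                                   k_inh1 = NA_real_, k_inh2 = NA_real_),
                         time_unit = "h") {
  sp <- data.frame(
    index = 1:7,
    name = c("piperidine", "fmoc_piperidine", "p_nitrophenyl_acetate",
             "phenyl_acetate", "n_methylpiperidine", "dibenzofulvene",
             "n_acetyl_piperidine"),
    constant = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  rx <- list(
    reaction(c(fmoc_piperidine = 1),
             c(piperidine = 1, dibenzofulvene = 1),
             rate_constant = "k_tr",
             exponents = c(fmoc_piperidine = 1, n_methylpiperidine = 1),
             label = "trigger"),
    reaction(c(piperidine = 1, fmoc_piperidine = 1),
             c(piperidine = 2, dibenzofulvene = 1),
             rate_constant = "k_ac", label = "autocatalysis"),
    reaction(c(piperidine = 1, p_nitrophenyl_acetate = 1),
             c(n_acetyl_piperidine = 1),
             rate_constant = "k_inh1", label = "fast_inhibition"),
    reaction(c(piperidine = 1, phenyl_acetate = 1),
             c(n_acetyl_piperidine = 1),
             rate_constant = "k_inh2", label = "slow_inhibition"))
  crn_network(sp, rx, kappa, time_unit = time_unit)
}

#' Self-contained toy oscillator fixture
#'
#' The Fmoc-piperidine network structure with a synthetic rate-constant set
#' and flow conditions found once by numerical search
#' (`inst/scripts/find_toy_oscillator.R`) to produce sustained limit-cycle
#' oscillations in a CSTR, with a period of a few hours. All package tests run
#' on this fixture so that no external parameterization is required.
#'
#' @return list with components `network` (a [crn_network()], time unit
#'   hours), `y0_flow` (reactor start-up state), `flow`
#'   ([flow_conditions()]), `y0_batch` (a single-pulse closed-reactor initial
#'   state), `horizon_flow` and `horizon_batch` (solve horizons, hours).
#' @export
toy_oscillator <- function() {
  kappa <- c(k_tr = 5, k_ac = 300, k_inh1 = 1700, k_inh2 = 3)
  net <- fmoc_network(kappa, time_unit = "h")
  # CSTR steady state is Hopf-unstable here: sustained limit cycle with a
  # period near 3.1 h and ~0.07 M dibenzofulvene amplitude.
  y_in <- c(piperidine = 0, fmoc_piperidine = 0.15,
            p_nitrophenyl_acetate = 0.05, phenyl_acetate = 2.5,
            n_methylpiperidine = 0, dibenzofulvene = 0,
            n_acetyl_piperidine = 0)
  y0_flow <- y_in
  y0_flow["n_methylpiperidine"] <- 0.025
  # closed-reactor single pulse: piperidine peaks near t = 3.7 h and the
  # Fmoc pool is exhausted within the 6 h horizon
  y0_batch <- c(piperidine = 0, fmoc_piperidine = 0.1,
                p_nitrophenyl_acetate = 0.05, phenyl_acetate = 1.0,
                n_methylpiperidine = 0.02, dibenzofulvene = 0,
                n_acetyl_piperidine = 0)
  list(network = net,
       y0_flow = y0_flow,
       flow = flow_conditions(y_in = unname(y_in), D = 1.0),
       y0_batch = y0_batch,
       horizon_flow = 40,
       horizon_batch = 6)
}
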