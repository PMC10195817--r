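# Synthetic titration curves under the quadratic (ligand-depletion) binding
# isotherm, optionally with the linear baseline term of the modified model.

#' Simulate a titration curve
#'
#' Computes the bound-complex concentration from the quadratic tight-binding
#' isotherm ([eq1_bound()]) at each total titrant concentration, converts it
#' to a signal `f_free + (f_bound - f_free) * bound / fixed_partner`
#' (plus the linear baseline term for the modified model), and adds Gaussian
#' noise.  A 16-step two-fold serial dilution from 10 µM against a 50 nM
#' fixed labelled partner mirrors a typical microscale-thermophoresis
#' self-association design.
#'
#' @param kd dissociation constant (µM, > 0).
#' @param design total titrant concentrations (µM, > 0); default the
#'   16-step two-fold dilution from 10 µM.
#' @param fixed_partner fixed (labelled) partner concentration (µM);
#'   default 0.05 (50 nM).
#' @param f_free,f_bound signal of the free and fully bound partner.
#' @param model `"eq1"` (pure quadratic) or `"eq2"` (adds `a + b * conc`).
#' @param a,b linear-term parameters, required for `"eq2"`.
#' @param linear_in for `"eq2"`: whether the linear term multiplies the
#'   fixed partner concentration (`"partner"`, the printed form, a constant
#'   offset under this design) or the varying titrant (`"titrant"`).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param n_replicates number of replicate curves.
#' @param seed integer seed.
#' @return a [titration_curve()] with a `replicate` column; attribute
#'   `truth` stores the generating parameters.
#' @export
simulate_titration <- function(kd, design = 10 / 2^(15:0),
                               fixed_partner = 0.05,
                               f_free = 0, f_bound = 1,
                               model = c("eq1", "eq2"), a = NULL, b = NULL,
                               linear_in = c("partner", "titrant"),
                               noise_sd = 0, n_replicates = 1, seed = NULL) {
  model <- match.arg(model)
  linear_in <- match.arg(linear_in)
  check_number(kd, "kd", lower = .Machine$double.eps)
  check_number(design, "design", lower = .Machine$double.eps)
  check_number(fixed_partner, "fixed_partner", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (model == "eq2" && (is.null(a) || is.null(b))) {
    stop_param("model eq2 requires a and b")
  }
  design <- sort(design)
  with_seed_or_current(seed, {
    bound <- eq1_bound(design, fixed_partner, kd)
    sig <- f_free + (f_bound - f_free) * bound / fixed_partner
    if (model == "eq2") {
      sig <- sig + a + b * switch(linear_in, partner = fixed_partner,
                                  titrant = design)
    }
    conc <- rep(design, n_replicates)
    repl <- rep(seq_len(n_replicates), each = length(design))
    signal <- rep(sig, n_replicates) +
      if (noise_sd > 0) stats::rnorm(length(conc), 0, noise_sd) else 0
    tc <- titration_curve(conc, signal, fixed_partner = fixed_partner,
                          replicate = repl)
    attr(tc, "truth") <- list(kd = kd, f_free = f_free, f_bound = f_bound,
                              model = model, a = a, b = b,
                              linear_in = linear_in, noise_sd = noise_sd)
    tc
  })
}
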