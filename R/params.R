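#' Model parameters
#'
#' Every constant of the five-species front model. Units: lengths in domain
#' units (the slab is `[0, b_omega]`, default length 1, to be read as roughly
#' 100 cell diameters), time in hours, densities scaled so that the tumor
#' carrying capacity and the undegraded ECM are O(1).
#'
#' The defaults below are the package's own calibration (a versioned default
#' configuration, not literature values). They were chosen so that (i) the
#' front traverses an O(1) fraction of the domain in 15 h, (ii) the TM band
#' spans 5–7 cell diameters with a cell diameter of 0.01 domain units, and
#' (iii) the baseline run develops the characteristic front pattern: an MMP1
#' peak on the TM band shifted migration-ward of the tumor shoulder, an
#' active-integrin plateau on the band, and integrin exchange localized at
#' the support edge.
#'
#' @param nu_N,m_N,v_N Tumor flux-saturation triplet: viscosity-like
#'   coefficient, saturation constant and maximum propagation speed
#'   (length/h). The tumor flux is
#'   \eqn{J = \nu N N_x / \sqrt{m^2 + (\nu/v)^2 N_x^2}}, so `|J| <= v_N * N`.
#' @param a1 Chemotactic sensitivity to the MMP1 gradient.
#' @param a2 Haptotactic sensitivity to the active-integrin gradient.
#' @param a3 Logistic growth rate (1/h).
#' @param K_N Tumor carrying capacity.
#' @param nu_P,m_P,v_P Flux-saturation triplet for MMP1.
#' @param a4 MMP1 production rate on the TM band (per unit ECM and activity).
#' @param a5 MMP1 degradation rate per unit tumor density (1/h).
#' @param a6 ECM degradation rate per unit MMP1 (1/h).
#' @param E0 Undegraded ECM level in healthy tissue.
#' @param E_basal Residual ECM level maintained inside the tumor bulk.
#' @param a7 Integrin activation rate (per unit ECM and activity).
#' @param a8 Integrin inactivation rate inside the support (1/h).
#' @param a9 Exocytosis (integrin production) rate (1/h).
#' @param K_I Integrin saturation level (`A + I` relaxes toward `K_I` on the
#'   tumor region).
#' @param v_Int Integrin transport speed (length/h), carrying membrane
#'   receptors with the migrating cells.
#' @param transport_direction `"toward_front"` (default; profiles advected in
#'   the migration direction, +x) or `"toward_bulk"` (the literal sign
#'   `+v_Int du/dx`). See [integrin_transport()].
#' @param h_p Maximum microtube length; the TM band is `[b_N, b_N + h_p]`.
#'   Default 0.06 domain units = 6 cell diameters.
#' @param eps_F,alpha_F Regularization and exponent of the activity
#'   functional \eqn{F(N) = (N * I_{[-h_p,h_p]} + \epsilon)^{-\alpha_F}}.
#' @param delta_N Support-detection threshold for [tumor_support()].
#' @param A_basal,I_basal Basal active/inactive integrin levels (imposed
#'   through initial conditions, not source terms).
#' @param porosity_on Logical; when `TRUE` the tumor saturation speed `v_N`
#'   is replaced node-wise by the porosity map [porosity_velocity()].
#' @param reduced_model Logical; when `TRUE` the tumor equation keeps only
#'   the flux-saturated term (no taxis, no growth), the comparison model of
#'   the porosity study.
#' @param eps_min,eps_max Porosity band of the velocity ramp (void fractions;
#'   defaults 0.50 and 0.66).
#' @param v_por_min,v_por_max Speeds at the ends of the porosity ramp;
#'   default `v_N` and `1.5 * v_N`.
#' @return A validated `gb_params` list.
#' @examples
#' p <- model_params(a1 = 0.002)
#' p$a1
#' @export
model_params <- function(nu_N = 0.005, m_N = 1, v_N = 0.03,
                         a1 = 5e-4, a2 = 5e-4, a3 = 0.3, K_N = 1,
                         nu_P = 0.005, m_P = 1, v_P = 0.05,
                         a4 = 0.05, a5 = 1,
                         a6 = 1, E0 = 1, E_basal = 0.15,
                         a7 = 5, a8 = 1, a9 = 2, K_I = 1,
                         v_Int = 0.035,
                         transport_direction = c("toward_front", "toward_bulk"),
                         h_p = 0.06, eps_F = 0.1, alpha_F = 1.5,
                         delta_N = 1e-3,
                         A_basal = 0.2, I_basal = 0.1,
                         porosity_on = FALSE, reduced_model = FALSE,
                         eps_min = 0.50, eps_max = 0.66,
                         v_por_min = NULL, v_por_max = NULL) {
  transport_direction <- match.arg(transport_direction)
  p <- list(nu_N = nu_N, m_N = m_N, v_N = v_N,
            a1 = a1, a2 = a2, a3 = a3, K_N = K_N,
            nu_P = nu_P, m_P = m_P, v_P = v_P,
            a4 = a4, a5 = a5, a6 = a6, E0 = E0, E_basal = E_basal,
            a7 = a7, a8 = a8, a9 = a9, K_I = K_I, v_Int = v_Int,
            transport_direction = transport_direction,
            h_p = h_p, eps_F = eps_F, alpha_F = alpha_F,
            delta_N = delta_N, A_basal = A_basal, I_basal = I_basal,
            porosity_on = isTRUE(porosity_on),
            reduced_model = isTRUE(reduced_model),
            eps_min = eps_min, eps_max = eps_max,
            v_por_min = if (is.null(v_por_min)) v_N else v_por_min,
            v_por_max = if (is.null(v_por_max)) 1.5 * v_N else v_por_max)
  validate_params(p)
}

#' @rdname model_params
#' @param p A parameter list to validate.
#' @export
validate_params <- function(p) {
  num <- setdiff(names(p), c("transport_direction", "porosity_on",
                             "reduced_model"))
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm))
    if (v < 0)
      stop(sprintf("parameter '%s' must be nonnegative", nm))
  }
  for (nm in c("K_N", "K_I", "m_N", "m_P", "v_N", "v_P", "eps_F"))
    if (p[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be strictly positive", nm))
  if (p$delta_N >= p$K_N)
    stop("parameter 'delta_N' must be below the carrying capacity K_N")
  if (!(p$eps_min >= 0 && p$eps_min < p$eps_max && p$eps_max <= 1))
    stop("porosity band needs 0 <= eps_min < eps_max <= 1")
  structure(p, class = "gb_params")
}

#' @export
print.gb_params <- function(x, ...) {
  cat("<gb_params>\n")
  nm <- setdiff(names(x), c("transport_direction", "porosity_on",
                            "reduced_model"))
  vals <- vapply(nm, function(n) sprintf("%s = %g", n, x[[n]]), "")
  cat(" ", paste(vals, collapse = ", "), "\n")
  cat(sprintf("  transport: %s, porosity map: %s, reduced model: %s\n",
              x$transport_direction, x$porosity_on, x$reduced_model))
  invisible(x)
}
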