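# independent reference integrator: scipy BDF through the system python
scipy_reference <- function(scheme, y0, times, rtol = 1e-10, atol = 1e-12) {
  script <- '
import json, sys
import numpy as np
from scipy.integrate import solve_ivp
cfg = json.load(open(sys.argv[1]))
N = np.array(cfg["stoich"], float)
ri = np.array(cfg["ri"], int) - 1
k = np.array(cfg["k"], float)
y0 = np.array(cfg["y0"], float)
times = np.array(cfg["times"], float)
def rhs(t, y):
    flux = k * y[ri[0]]
    m = ri[1] >= 0
    flux[m] = flux[m] * y[ri[1][m]]
    return N @ flux
sol = solve_ivp(rhs, (0, times[-1]), y0, method="BDF", t_eval=times,
                rtol=float(np.ravel(cfg["rtol"])[0]),
                atol=float(np.ravel(cfg["atol"])[0]))
json.dump({"y": sol.y.T.tolist(), "ok": bool(sol.success)},
          open(sys.argv[2], "w"))
'
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(stoich = unname(scheme$stoich),
                            ri = unname(scheme$reactant_idx),
                            k = scheme$rates, y0 = unname(y0),
                            times = times, rtol = rtol, atol = atol),
                       fin, digits = NA)
  status <- system2("python", c(py, fin, fout), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  stopifnot(isTRUE(res$ok))
  y <- res$y
  colnames(y) <- scheme$species
  y
}

# brute-force binding equilibrium of the single-substrate scheme with
# catalysis switched off: root-find on free substrate concentration
binding_equilibrium <- function(params, S_tot, E_tot) {
  stopifnot(params$kcat_E == 0, params$kcat_Estar == 0)
  keq_E <- params$kE_fwd / params$kE_rev
  k_off_star <- cycle_closure(params)
  free_E <- function(S) {
    # E * (1 + KeqE + k1 S/k_off + KeqE k1 S / k_off*) = E_tot
    E_tot / (1 + keq_E + params$k1 * S / params$k_off +
               keq_E * params$k1 * S / k_off_star)
  }
  g <- function(S) {
    E <- free_E(S)
    ES <- params$k1 * E * S / params$k_off
    EstarS <- params$k1 * keq_E * E * S / k_off_star
    S + ES + EstarS - S_tot
  }
  S <- stats::uniroot(g, c(0, S_tot), tol = 1e-14)$root
  E <- free_E(S)
  c(E = E, Estar = keq_E * E, ES = params$k1 * E * S / params$k_off,
    EstarS = params$k1 * keq_E * E * S / k_off_star, S = S, P = 0)
}
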