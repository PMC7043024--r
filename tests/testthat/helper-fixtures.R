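# shared fixtures built in code

# a generic, well-conditioned two-state parameter set (fast enough that
# short synthetic curves carry signal)
quick_params <- function(kcat_E = 1, k_off = 5, kE_fwd = 0.003,
                         kE_rev = 0.003, kES_fwd = 0.003, kES_rev = 0.003,
                         kcat_Estar = 0.5, k1 = 0.2)
  rate_params(kcat_E = kcat_E, k_off = k_off, kE_fwd = kE_fwd,
              kE_rev = kE_rev, kES_fwd = kES_fwd, kES_rev = kES_rev,
              kcat_Estar = kcat_Estar, k1 = k1)

# a short experiment design for fast fitting tests
quick_design <- function(S0 = 150, E0 = 0.2, n_points = 30, sigma = 1,
                         seed = 1L, substrate = "K4meK9", deadtime = 30)
  experiment_design(substrate = substrate, S0 = S0, E0 = E0, interval = 61,
                    duration = n_points * 61, deadtime = deadtime,
                    sigma = sigma, seed = seed)

# scale all four exchange rates by M, preserving both Keq values
scale_exchange <- function(p, M)
  rate_params(kcat_E = p$kcat_E, k_off = p$k_off,
              kE_fwd = p$kE_fwd * M, kE_rev = p$kE_rev * M,
              kES_fwd = p$kES_fwd * M, kES_rev = p$kES_rev * M,
              kcat_Estar = p$kcat_Estar, k1 = p$k1)

modify_design <- function(des, ...)
  do.call(experiment_design, utils::modifyList(unclass(des), list(...)))

# internal helpers under test
update_rates_test <- function(p, new) nmrkin:::update_rates(p, new)
initial_state_test <- function(scheme, S0, E0)
  nmrkin:::initial_state(scheme, S0, E0)

# random cycle-closed parameter sets for property-style loops
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    rate_params(kcat_E = 10^runif(1, -2, 1), k_off = 10^runif(1, -1, 2),
                kE_fwd = 10^runif(1, -4, -1), kE_rev = 10^runif(1, -4, -1),
                kES_fwd = 10^runif(1, -4, -1), kES_rev = 10^runif(1, -4, -1),
                kcat_Estar = 10^runif(1, -3, 0)))
}
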