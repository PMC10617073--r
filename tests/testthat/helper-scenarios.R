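# Simulation scenarios for hazard-ratio recovery: each uses a published
# effect estimate as the generating truth on one transition.
recovery_scenarios <- list(
  hypertension_good_poor = list(hr = 2.34, pair = c(1, 2),
                                covariate = "hypertension", prevalence = 0.47,
                                n = 2000),
  af_poor_death = list(hr = 3.39, pair = c(2, 3), covariate = "af",
                       prevalence = 0.319, n = 3000),
  age_good_poor = list(hr = 1.73, pair = c(1, 2), covariate = "age60",
                       prevalence = 0.5, n = 2000),
  diabetes_poor_good = list(hr = 0.54, pair = c(2, 1), covariate = "diabetes",
                            prevalence = 0.322, n = 3000)
)

# panel whose state occupancy totals equal the published ones:
# 1854 good, 1102 poor, 104 death observations; baseline 93 good, 205 poor
panel_published_occupancy <- function() {
  visits <- list()
  good_len <- rep(c(20L, 19L), c(87L, 6L))          # sums to 1854
  for (k in good_len)
    visits <- c(visits, list(list(time = 3 * (seq_len(k) - 1),
                                  state = rep(1L, k))))
  poor_len <- rep(c(6L, 5L), c(77L, 128L))          # sums to 1102
  dies <- rep(c(TRUE, FALSE), c(104L, 101L))
  for (i in seq_along(poor_len)) {
    k <- poor_len[i]
    st <- rep(2L, k)
    tt <- 3 * (seq_len(k) - 1)
    if (dies[i]) { st <- c(st, 3L); tt <- c(tt, max(tt) + 3) }
    visits <- c(visits, list(list(time = tt, state = st)))
  }
  panel_from_visits(visits)
}
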