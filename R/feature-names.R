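## Canonical feature schema: 515 names across nine domains, in the fixed
## extraction order. Every feature table, model and ranking in the package
## uses exactly this order.

FEATURE_DOMAINS <- c(
  time_interval = 20L, freq_state = 308L, amplitude = 12L, energy = 47L,
  freq_record = 27L, cepstrum = 65L, cyclostationarity = 4L, hos = 16L,
  entropy = 16L
)

band_edges <- function() seq(10, 820, by = 30) # 27 bands of 30 Hz width

state_grid <- function() seq(30, 790, by = 10) # 77 spectral sample points

band_label <- function(i) {
  e <- band_edges()
  sprintf("%d_%dHz", e[i], e[i + 1])
}

time_interval_names <- c(
  "m_RR", "sd_RR", "m_IntS1", "sd_IntS1", "m_IntS2", "sd_IntS2",
  "m_IntSys", "sd_IntSys", "m_IntDia", "sd_IntDia",
  "m_Ratio_SysRR", "sd_Ratio_SysRR", "m_Ratio_DiaRR", "sd_Ratio_DiaRR",
  "m_Ratio_SysDia", "sd_Ratio_SysDia", "m_Ratio_S1RR", "sd_Ratio_S1RR",
  "m_Ratio_S2RR", "sd_Ratio_S2RR"
)

amplitude_pairs <- c("Amp_SysS1", "Amp_DiaS2", "Amp_S1S2", "Amp_S1Dia",
                     "Amp_SysDia", "Amp_S2Sys")

amplitude_names <- as.vector(rbind(paste0("m_", amplitude_pairs),
                                   paste0("sd_", amplitude_pairs)))

energy_ratio_pairs <- c(
  "S1_cycle", "S2_cycle", "sys_cycle", "dia_cycle",
  "S1_S2", "S1_sys", "S1_dia", "S2_sys", "S2_dia", "dia_sys"
)

#' Canonical names and domains of the 515 features
#'
#' @return Data frame with columns `name` and `domain` (one of
#'   `time_interval`, `freq_state`, `amplitude`, `energy`, `freq_record`,
#'   `cepstrum`, `cyclostationarity`, `hos`, `entropy`), 515 rows, in the
#'   fixed extraction order.
#' @export
pcg_feature_names <- function() {
  freq_state <- as.vector(vapply(
    c("S1", "sys", "S2", "dia"),
    function(s) sprintf("Spec_%s_%dHz", s, state_grid()),
    character(77)
  ))
  energy <- c(
    sprintf("Ratio_band_energy_%s", vapply(1:27, band_label, "")),
    as.vector(rbind(paste0("m_Ratio_state_energy_", energy_ratio_pairs),
                    paste0("sd_Ratio_state_energy_", energy_ratio_pairs)))
  )
  freq_record <- sprintf("Ratio_spec_mag_%s", vapply(1:27, band_label, ""))
  cepstrum <- as.vector(vapply(
    c("record", "S1", "sys", "S2", "dia"),
    function(s) sprintf("Cep_%s_%d", s, 1:13),
    character(13)
  ))
  cyclo <- c("m_cyclostationarity_1", "sd_cyclostationarity_1",
             "m_cyclostationarity_2", "sd_cyclostationarity_2")
  hos <- as.vector(vapply(
    c("S1", "S2", "sys", "dia"),
    function(s) c(sprintf("m_%s_skewness", s), sprintf("sd_%s_skewness", s),
                  sprintf("m_%s_kurtosis", s), sprintf("sd_%s_kurtosis", s)),
    character(4)
  ))
  entropy <- c(
    as.vector(vapply(c("S1", "S2", "sys", "dia"),
                     function(s) c(sprintf("m_SampEn_%s", s),
                                   sprintf("sd_SampEn_%s", s)),
                     character(2))),
    as.vector(vapply(c("S1", "S2", "sys", "dia"),
                     function(s) c(sprintf("m_FuzzyMEn_%s", s),
                                   sprintf("sd_FuzzyMEn_%s", s)),
                     character(2)))
  )
  names_all <- c(time_interval_names, freq_state, amplitude_names, energy,
                 freq_record, cepstrum, cyclo, hos, entropy)
  stopifnot(length(names_all) == 515L, !anyDuplicated(names_all))
  data.frame(
    name = names_all,
    domain = rep(names(FEATURE_DOMAINS), FEATURE_DOMAINS)
  )
}

#' Per-domain feature counts
#'
#' @return Named integer vector over the nine domains (sums to 515).
#' @export
pcg_domain_counts <- function() FEATURE_DOMAINS
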