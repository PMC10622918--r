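#' Published bin-mean abundances and rates for CCE picoplankton
#'
#' Mean (+/- SEM) cell abundance, instantaneous growth rate (mu),
#' microzooplankton grazing mortality (m), and net growth (mu - m) of the
#' four picoplankton populations -- heterotrophic bacteria (HBAC),
#' *Prochlorococcus* (PRO), *Synechococcus* (SYN), and photosynthetic
#' picoeukaryotes (PEUK) -- observed in dilution experiments across the
#' southern California Current Ecosystem (CCE), summarised in three
#' primary-production classes (PP < 10, 10--100, and > 100 mg C m-3 d-1).
#'
#' These published bin means serve two roles in the package: they anchor
#' the synthetic cruise generator's true-rate trends
#' ([true_rates_from_pp()]), and they are the inputs to the
#' shared-predation projection arithmetic ([project_shared_predation()]).
#' *Prochlorococcus* is absent from the high-production class (cold
#' upwelled water); its rates there are `NA` ("nd").
#'
#' @return A tibble with one row per production class x population:
#'   `pp_bin`, `population`, `abundance` (cells mL-1), `abundance_sem`,
#'   `mu`, `mu_sem`, `m`, `m_sem`, `net`, `net_sem` (all rates d-1).
#' @seealso [cce_mortality_ratios()], [true_rates_from_pp()]
#' @export
#' @examples
#' cce_picoplankton_rates()
cce_picoplankton_rates <- function() {
  tribble_cols <- c("pp_bin", "population", "abundance_1e3", "abundance_sem_1e3",
                    "mu", "mu_sem", "m", "m_sem", "net", "net_sem")
  x <- tibble::tribble(
    ~pp_bin,      ~population, ~abundance_1e3, ~abundance_sem_1e3, ~mu,  ~mu_sem, ~m,   ~m_sem, ~net,  ~net_sem,
    "PP<10",      "HBAC",      798,            65,                 0.23, 0.02,    0.21, 0.02,   0.02,  0.02,
    "PP<10",      "PRO",       153,            13,                 0.46, 0.08,    0.38, 0.06,   0.08,  0.04,
    "PP<10",      "SYN",       17,             4,                  0.48, 0.07,    0.57, 0.09,  -0.09,  0.05,
    "PP<10",      "PEUK",      6.3,            0.6,                0.42, 0.08,    0.46, 0.08,  -0.04,  0.03,
    "10<PP<100",  "HBAC",      1480,           160,                0.42, 0.03,    0.34, 0.02,   0.08,  0.02,
    "10<PP<100",  "PRO",       54,             13,                 0.48, 0.05,    0.34, 0.04,   0.13,  0.04,
    "10<PP<100",  "SYN",       49,             7,                  0.38, 0.02,    0.30, 0.02,   0.08,  0.02,
    "10<PP<100",  "PEUK",      26,             3,                  0.44, 0.04,    0.34, 0.02,   0.09,  0.04,
    "PP>100",     "HBAC",      1820,           240,                0.79, 0.07,    0.61, 0.07,   0.18,  0.03,
    "PP>100",     "PRO",       0,              0,                  NA,   NA,      NA,   NA,     NA,    NA,
    "PP>100",     "SYN",       13,             6,                  0.38, 0.04,    0.19, 0.03,   0.19,  0.03,
    "PP>100",     "PEUK",      22,             5,                  0.45, 0.06,    0.30, 0.04,   0.15,  0.06
  )
  stopifnot(identical(names(x), tribble_cols))
  dplyr::mutate(x,
    abundance = .data$abundance_1e3 * 1e3,
    abundance_sem = .data$abundance_sem_1e3 * 1e3,
    .keep = "unused", .before = "mu"
  )
}

#' Published mean mortality ratios relative to heterotrophic bacteria
#'
#' Mean (+/- SEM) of per-experiment grazing-mortality ratios
#' m(population) / m(HBAC) at the low- and high-production ends of the CCE
#' gradient. Because the ratio is averaged per experiment, these values
#' differ from the ratio of the bin-mean mortalities in
#' [cce_picoplankton_rates()] (Jensen's inequality); the per-experiment
#' means are the ones used for shared-predation scaling.
#'
#' @return A tibble: `population`, `ratio_low` / `ratio_low_sem`
#'   (PP < 10 mg C m-3 d-1), `ratio_high` / `ratio_high_sem` (PP > 100).
#' @seealso [project_shared_predation()]
#' @export
cce_mortality_ratios <- function() {
  tibble::tribble(
    ~population, ~ratio_low, ~ratio_low_sem, ~ratio_high, ~ratio_high_sem,
    "SYN",       3.9,        0.6,            0.32,        0.05,
    "PEUK",      2.4,        0.4,            0.62,        0.11
  )
}

# Observed envelope of environmental variables and abundances across the
# eight CCE process cruises; the generator keeps everything inside it.
cce_envelope <- function() {
  list(
    temperature = c(11, 19.5),      # degC
    nitrate     = c(0, 14),         # uM
    chla        = c(0.05, 14),      # mg m-3
    pp          = c(1.8, 367),      # mg C m-3 d-1
    abundance   = list(             # cells mL-1
      HBAC = c(271e3, 6140e3),
      PRO  = c(0, 323e3),
      SYN  = c(1.3e3, 246e3),
      PEUK = c(0.8e3, 145e3)
    )
  )
}
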