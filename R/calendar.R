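# Leapless 365-day calendar used throughout (synthetic mode drops Feb 29).

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
DAY_MONTH <- rep(seq_len(12L), MONTH_DAYS) # day-of-year -> month

# Seasonal blocks: 4 groups of 3 months starting in January.
SEASON_NAMES <- c("jfm", "amj", "jas", "ond")
SEASON_DAYS <- list(
  jfm = 1:90,
  amj = 91:181,
  jas = 182:273,
  ond = 274:365
)

# Chill season: Oct 1 of the prior year through Mar 31 of the current year.
CHILL_PRIOR_DAYS <- 274:365 # Oct-Dec of prior year (92 days)
CHILL_CURRENT_DAYS <- 1:90  # Jan-Mar of current year (90 days)

CONTEXT_VARS <- c("gdd", "season_length", "hdh", "chill", "precip_range")
GENERIC_VARS <- c(
  paste0("tmean_", SEASON_NAMES),
  paste0("prcp_", SEASON_NAMES)
)

variable_names <- function(mode = c("context", "generic")) {
  mode <- match.arg(mode)
  if (mode == "context") CONTEXT_VARS else GENERIC_VARS
}
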