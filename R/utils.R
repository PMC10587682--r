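#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats median optim optimize qnorm quantile rnorm runif sd
#'   setNames var pchisq shapiro.test wilcox.test cor cov
#' @importFrom utils modifyList head tail
NULL

# Recognized oral formulations, slowest-release last two
.formulations <- c("syrup", "sprinkle", "capsule", "conventional_tablet",
                   "enteric_coated", "sustained_release")

# Covariate columns every model-facing function may consult
.covariate_cols <- c("sex", "age", "weight", "albumin", "daily_dose",
                     "daily_dose_per_kg", "formulation", "cbz", "pb", "pht",
                     "ltg", "clb", "other_comed", "uncontrolled_epilepsy",
                     "pma")

.flag_cols <- c("cbz", "pb", "pht", "ltg", "clb", "other_comed",
                "uncontrolled_epilepsy")

# Weeks per year used when deriving postmenstrual age from postnatal age
.weeks_per_year <- 365.25 / 7

stopifnot_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (any(!is.finite(x)) || any(x <= 0)) {
      abort(sprintf("`%s` must be strictly positive and finite.", nm),
            class = "vpaeval_domain_error")
    }
  }
  invisible(TRUE)
}

# set.seed without clobbering the caller's RNG state; NULL seed = use
# whatever stream is active
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(ifelse(is.na(x), FALSE, x != 0))
  x <- tolower(as.character(x))
  x %in% c("1", "true", "yes", "y")
}
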