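#' Read a life table from CSV
#'
#' Expects a two-column CSV with header `age,q_annual`: integer age in years
#' and the annual probability of death at that age (a standard period life
#' table `q_x` column). Ages must be contiguous and probabilities in [0, 1].
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `age` (integer) and `q_annual`, of
#'   class `txace_life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "q_annual") %in% names(lt))) {
    stop("life table must have columns 'age' and 'q_annual'")
  }
  as_life_table(lt[, c("age", "q_annual")])
}

#' Coerce a data frame to a validated life table
#' @param lt A data frame with columns `age` and `q_annual`.
#' @return The validated `txace_life_table` object.
#' @export
as_life_table <- function(lt) {
  lt$age <- as.integer(lt$age)
  lt <- lt[order(lt$age), , drop = FALSE]
  if (any(diff(lt$age) != 1L)) stop("life table ages must be contiguous")
  if (any(lt$q_annual < 0 | lt$q_annual > 1)) {
    stop("life table q_annual values must lie in [0, 1]")
  }
  rownames(lt) <- NULL
  class(lt) <- c("txace_life_table", "data.frame")
  lt
}

#' Synthetic UK-style life table (Gompertz-Makeham)
#'
#' Generates an all-persons period life table from a Gompertz-Makeham
#' mortality law, h(x) = A + B c^x, with annual death probability
#' q_x = 1 - exp(-(A + B c^x (c - 1) / ln c)). The default parameters were
#' fitted to published UK national all-persons mortality rates (background
#' rate A = 1.0e-3, level B = 7.4e-6, rate of ageing c = 1.116), giving a
#' period life expectancy at age 58 of about 25 years. The table is forced
#' to absorb at `terminal_age` (q = 1 there).
#'
#' This generator backs the vendored fixture shipped with the package
#' (`life_table_uk_synthetic.csv`) and supports fully synthetic testing at
#' other mortality levels.
#'
#' @param ages Integer vector of contiguous ages.
#' @param a Makeham (age-independent) hazard component.
#' @param b Gompertz level parameter.
#' @param c_rate Gompertz rate of ageing (per year of age).
#' @param terminal_age Age at which q is set to 1 (absorption).
#' @return A `txace_life_table` data frame.
#' @export
#' @examples
#' lt <- gompertz_makeham_life_table()
#' lt[lt$age == 58, ]
gompertz_makeham_life_table <- function(ages = 35:100, a = 1.0e-3,
                                        b = 7.4e-6, c_rate = 1.116,
                                        terminal_age = max(ages)) {
  stopifnot(a >= 0, b > 0, c_rate > 1)
  ages <- as.integer(ages)
  cum_haz <- a + b * c_rate^ages * (c_rate - 1) / log(c_rate)
  q <- 1 - exp(-cum_haz)
  q[ages >= terminal_age] <- 1
  as_life_table(data.frame(age = ages, q_annual = q))
}

#' The vendored UK-style life table fixture
#'
#' Reads the synthetic all-persons life table shipped with the package
#' (ages 35-100, absorption at 100), generated once from
#' [gompertz_makeham_life_table()] with its default parameters.
#'
#' @return A `txace_life_table` data frame.
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_uk_synthetic.csv",
                              package = "txace", mustWork = TRUE))
}

# fast lookup vector: q_lookup(lt)[age + 1] gives q at integer age
.q_lookup <- function(lt) {
  qv <- rep(NA_real_, max(lt$age) + 1L)
  qv[lt$age + 1L] <- lt$q_annual
  qv
}
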