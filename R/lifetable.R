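#' Synthetic national life table
#'
#' A stand-in for a national single-year life table (columns `age`, `sex`,
#' `qx`), generated from a Gompertz-Makeham law fitted loosely to
#' contemporary England & Wales mortality levels:
#' `mu(age) = a + b * exp(c * age)` with sex-specific `b`.  It is synthetic
#' and clearly labelled as such; [read_life_table()] accepts a real life
#' table in the same delimited-text format as a drop-in replacement.
#'
#' @param max_age last age with a qx entry (default 99; death is certain at
#'   the model horizon regardless).
#' @return data.frame with columns `age`, `sex`, `qx`.
#' @export
synthetic_life_table <- function(max_age = 99) {
  age <- 0:max_age
  make <- function(b) {
    mu <- 2e-4 + b * exp(0.093 * age)
    mu[age < 1] <- mu[age < 1] + 0.004      # infant mortality bump
    1 - exp(-mu)
  }
  rbind(
    data.frame(age = age, sex = "male", qx = make(3.4e-5)),
    data.frame(age = age, sex = "female", qx = make(2.1e-5))
  )
}

#' Read a life table from delimited text
#'
#' @param path tab- or comma-delimited file with columns `age`, `sex`
#'   (`male`/`female`) and `qx` (annual death probability).
#' @return data.frame with those columns.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(lt) == 1) lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "qx") %in% names(lt)))
  if (any(lt$qx < 0 | lt$qx >= 1)) stopf("life table qx must be in [0, 1)")
  lt
}

#' Convert a life table to a piecewise-constant mortality hazard
#'
#' Annual death probabilities become constant hazards on each single-year
#' age interval via `rate = -log(1 - qx)`.
#'
#' @param life_table data.frame as from [synthetic_life_table()].
#' @param sex `"male"` or `"female"`.
#' @return a [hazard_fn()].
#' @export
life_table_hazard <- function(life_table, sex) {
  lt <- life_table[life_table$sex == sex, ]
  lt <- lt[order(lt$age), ]
  hazard_fn(c(lt$age, max(lt$age) + 1), -log(1 - lt$qx))
}
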