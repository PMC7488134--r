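#' Health states and screening strategies
#'
#' The natural-history model of esophageal squamous cell carcinoma uses
#' eleven health states: disease-free (`NORMAL`), low-grade intraepithelial
#' neoplasia (`LGIN`), four cancer stages at diagnosis -- intraductal
#' carcinoma including high-grade neoplasia (`IC`), submucosal cancer
#' (`SM`), moderate stage IB--III (`MOD`) and advanced stage IV (`ADV`) --
#' the post-treatment disease-free / progression-free survival states
#' (`DFS_IC`, `DFS_SM`, `DFS_MOD`, `PFS_ADV`) and absorbing `DEATH`.
#'
#' `health_states()` returns the states in canonical matrix order.
#' `strategies()` returns the three policy arms: no screening (`NON_SCR`),
#' one-time endoscopic screening with annual follow-up of LGIN (`SCR_FOL`)
#' and one-time screening without follow-up (`SCR_NFOL`).
#'
#' @return A character vector of state or strategy names.
#' @export
#' @examples
#' health_states()
#' strategies()
health_states <- function() {
  c("NORMAL", "LGIN", "IC", "SM", "MOD", "ADV",
    "DFS_IC", "DFS_SM", "DFS_MOD", "PFS_ADV", "DEATH")
}

#' @rdname health_states
#' @export
strategies <- function() {
  c("NON_SCR", "SCR_FOL", "SCR_NFOL")
}

# states diagnosed as cancer (treatment states)
ec_states <- function() c("IC", "SM", "MOD", "ADV")

# states carrying an EC-specific death probability
ec_death_states <- function() c("SM", "DFS_SM", "MOD", "DFS_MOD", "ADV", "PFS_ADV")

#' Stage-class predicates
#'
#' `IC` and `SM` together form the early cancer stages; `MOD` and `ADV`
#' form the invasive stages.
#'
#' @param state Character vector of health-state names.
#' @return Logical vector.
#' @export
#' @examples
#' is_early_ec(c("IC", "MOD"))
is_early_ec <- function(state) {
  stopifnot(all(state %in% health_states()))
  state %in% c("IC", "SM")
}

#' @rdname is_early_ec
#' @export
is_invasive_ec <- function(state) {
  stopifnot(all(state %in% health_states()))
  state %in% c("MOD", "ADV")
}

assert_strategy <- function(strategy) {
  if (!(is.character(strategy) && length(strategy) == 1L &&
        strategy %in% strategies())) {
    stop("`strategy` must be one of ", paste(strategies(), collapse = ", "),
         call. = FALSE)
  }
  strategy
}

assert_state <- function(state) {
  if (!(is.character(state) && length(state) == 1L &&
        state %in% health_states())) {
    stop("`state` must be one of the 11 health states", call. = FALSE)
  }
  state
}
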