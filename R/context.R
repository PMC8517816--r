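#' Patient context profiles
#'
#' Only age group and gender enter the model as context: they select the
#' a-priori distribution of each dimension's immediate value. Exactly four
#' profiles exist.
#'
#' @format Character vector of the four profile keys.
#' @export
context_profiles <- c("man_over_18", "man_under_18",
                      "woman_over_18", "woman_under_18")

#' Build (or normalise) a context profile key
#'
#' @param gender "man" or "woman", or a full profile key such as
#'   "woman_under_18" (in which case `age_group` is ignored).
#' @param age_group "over_18" or "under_18".
#' @return One of [context_profiles].
#' @export
context_profile <- function(gender, age_group = NULL) {
  if (is.null(age_group)) {
    key <- as.character(gender)
    if (!key %in% context_profiles) {
      abort_emibayes("context", sprintf(
        "unknown context '%s' (expected one of: %s)",
        key, paste(context_profiles, collapse = ", ")))
    }
    return(key)
  }
  if (!gender %in% c("man", "woman")) {
    abort_emibayes("context", sprintf("unknown gender '%s'", gender))
  }
  if (!age_group %in% c("over_18", "under_18")) {
    abort_emibayes("context", sprintf("unknown age group '%s'", age_group))
  }
  paste(gender, age_group, sep = "_")
}
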