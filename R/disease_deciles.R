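#' Default ICD-10 code map for the top-10 causes of death
#'
#' Maps ten disease groups (the leading global causes of death in
#' high-income countries) to ICD-10 code prefixes: any diagnosis code
#' starting with one of a group's prefixes counts toward that group.
#' Intended as an overridable default.
#'
#' @return named list of character prefix vectors: CAD (ischaemic heart
#'   disease), STR (stroke), ALZ (dementias), LCX (lung cancers), COPD,
#'   LRTI (lower respiratory tract infections), CCX (colorectal cancers),
#'   DIA (diabetes mellitus), KID (kidney diseases), BCX (breast cancers).
#' @export
default_code_map <- function() {
  list(CAD = paste0("I2", 0:5),
       STR = paste0("I6", 0:9),
       ALZ = c("F01", "F03", "G30"),
       LCX = c("C33", "C34"),
       COPD = c(paste0("J4", 0:4), "J47"),
       LRTI = c(paste0("J0", 9), paste0("J1", 0:8), paste0("J2", 0:2)),
       CCX = paste0("C", 18:21),
       DIA = paste0("E1", 0:4),
       KID = c(paste0("N0", 0:9), paste0("N1", 0:9)),
       BCX = "C50")
}

#' Assign phenotype deciles
#'
#' Ranks participants by residualized phenotype and splits them into ten
#' approximately equal groups (sizes differ by at most one; when n is not
#' a multiple of ten, the lower deciles take the extra participants).
#' Decile 1 is the lowest phenotype level. Ties are broken by
#' participant_id so the assignment is deterministic under any input
#' order. Intended to be run separately within each sex.
#'
#' @param residuals data.frame (participant_id, residual), e.g. the
#'   age+SES residuals from [residualize()] with the decile spec.
#' @param n_groups number of groups (default 10).
#' @return input data.frame plus integer `decile`, in the input row order.
#' @export
assign_deciles <- function(residuals, n_groups = 10) {
  n <- nrow(residuals)
  if (n < n_groups)
    stop("need at least ", n_groups, " participants", call. = FALSE)
  ord <- order(residuals$residual, residuals$participant_id)
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  lab <- rep(seq_len(n_groups), sizes)
  residuals$decile <- integer(n)
  residuals$decile[ord] <- lab
  residuals
}

# Internal: map ICD-10 codes to disease groups; codes matching no prefix
# return NA.
.match_code_group <- function(codes, code_map) {
  out <- rep(NA_character_, length(codes))
  for (g in names(code_map)) {
    hit <- Reduce(`|`, lapply(code_map[[g]], function(p) startsWith(codes, p)))
    out[is.na(out) & hit] <- g
  }
  out
}

#' Disease-diagnosis frequency by phenotype decile
#'
#' For each sex, disease group and decile, the proportion of participants
#' with at least one diagnosis in the group (a participant counts once per
#' group regardless of repeat diagnoses; participants with no diagnosis
#' rows stay in the denominators). Diagnosis codes matching no map prefix
#' are ignored and counted.
#'
#' @param deciles data.frame with participant_id, sex and decile (from
#'   [assign_deciles()] run per sex, plus a sex column).
#' @param diagnoses long data.frame (participant_id, icd10_code).
#' @param code_map named list of ICD-10 prefixes, see [default_code_map()].
#' @return data.frame (sex, disease_group, decile, n_in_decile,
#'   n_diagnosed, frequency) with attribute `"n_unmapped"` — the number of
#'   diagnosis rows whose code matched no group.
#' @export
disease_frequency <- function(deciles, diagnoses,
                              code_map = default_code_map()) {
  .assert(all(c("participant_id", "sex", "decile") %in% names(deciles)),
          "deciles needs participant_id, sex, decile")
  dx <- diagnoses[diagnoses$participant_id %in% deciles$participant_id, ,
                  drop = FALSE]
  grp <- .match_code_group(dx$icd10_code, code_map)
  n_unmapped <- sum(is.na(grp))
  if (n_unmapped > 0)
    warning(n_unmapped, " diagnosis code(s) matched no disease group")

  groups <- names(code_map)
  out <- list()
  for (s in sort(unique(deciles$sex))) {
    ds <- deciles[deciles$sex == s, , drop = FALSE]
    denom <- table(factor(ds$decile, levels = sort(unique(deciles$decile))))
    for (g in groups) {
      pids <- unique(dx$participant_id[!is.na(grp) & grp == g])
      hit <- ds$decile[ds$participant_id %in% pids]
      num <- table(factor(hit, levels = names(denom)))
      out[[paste(s, g)]] <- data.frame(
        sex = s, disease_group = g,
        decile = as.integer(names(denom)),
        n_in_decile = as.integer(denom),
        n_diagnosed = as.integer(num),
        frequency = as.integer(num) / as.integer(denom),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "n_unmapped") <- n_unmapped
  res
}
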