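# Reading, validating, writing and harmonizing GWAS/pQTL summary statistics.
#
# The canonical in-memory record set is a data.frame with columns
#   variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#   pvalue, n
# wrapped, together with trait metadata, in a "study_sumstats" object.
# Effect sizes for case-control traits are log-odds throughout; odds
# ratios are derived only at reporting time.

.canonical_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pvalue", "n")
.mandatory_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "pvalue")

#' Column-name dialect for summary-statistics files
#'
#' Maps canonical field names to the column headers used in a particular
#' file. Defaults follow the common GWAS convention
#' `SNP, CHR, POS, EA, NEA, EAF, BETA, SE, P, N`.
#'
#' @param ... Named overrides, e.g. `variant_id = "rsid"`, `pvalue = "pval"`.
#'   Valid names: `variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @return Named list mapping canonical names to file column names.
#' @export
#' @examples
#' sumstats_dialect(variant_id = "rsid", pvalue = "p_value")
sumstats_dialect <- function(...) {
  d <- list(variant_id = "SNP", chrom = "CHR", pos = "POS",
            effect_allele = "EA", other_allele = "NEA", eaf = "EAF",
            beta = "BETA", se = "SE", pvalue = "P", n = "N")
  ov <- list(...)
  bad <- setdiff(names(ov), names(d))
  if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(d, ov)
}

#' Construct a study summary-statistics object
#'
#' @param records data.frame with the canonical columns (`eaf` and `n` may
#'   be `NA`). Rows violating record invariants are dropped with a message.
#' @param trait_name Label for the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param n_cases,n_controls Case/control counts; required (positive) when
#'   `trait_type = "case_control"`.
#' @param validate Drop invalid rows? (default `TRUE`).
#' @return Object of class `study_sumstats`: a list with elements
#'   `trait_name`, `trait_type`, `n_cases`, `n_controls`, `records`, and a
#'   `n_dropped` count from validation.
#' @export
study_sumstats <- function(records, trait_name,
                           trait_type = c("quantitative", "case_control"),
                           n_cases = NA_integer_, n_controls = NA_integer_,
                           validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "case_control" &&
      (is.na(n_cases) || is.na(n_controls) || n_cases <= 0 || n_controls <= 0))
    stop("case_control traits require positive n_cases and n_controls")
  for (col in setdiff(.canonical_cols, names(records)))
    records[[col]] <- NA
  records <- records[, .canonical_cols]
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele  <- toupper(as.character(records$other_allele))
  records$chrom <- as.character(records$chrom)
  n_dropped <- 0L
  if (validate) {
    v <- validate_records(records)
    records <- v$records
    n_dropped <- v$n_dropped
  }
  if (anyDuplicated(records$variant_id))
    stop("duplicate variant_id in '", trait_name, "'")
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 n_cases = n_cases, n_controls = n_controls,
                 records = records, n_dropped = n_dropped),
            class = "study_sumstats")
}

#' @export
print.study_sumstats <- function(x, ...) {
  cat("<study_sumstats> ", x$trait_name, " (", x$trait_type, "): ",
      nrow(x$records), " variants\n", sep = "")
  invisible(x)
}

# Row-level invariants. Inconsistent p vs |beta/se| only warns (to 1
# significant figure under the two-sided normal approximation); hard
# violations drop the row.
validate_records <- function(records) {
  keep <- !is.na(records$variant_id) &
    !is.na(records$beta) & !is.na(records$se) & records$se > 0 &
    !is.na(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1 &
    (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
    (is.na(records$pos) | records$pos >= 1) &
    records$effect_allele != records$other_allele
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped for invariant violations")
  records <- records[keep, , drop = FALSE]
  if (nrow(records)) {
    # Consistency of p with |beta/se| is checked on the z scale, which is
    # robust to the rounding of printed effect sizes at small p.
    z_imp <- abs(records$beta / records$se)
    z_p <- -stats::qnorm(pmin(records$pvalue, 1) / 2)
    bad <- is.finite(z_p) & abs(z_imp - z_p) > 0.1 * pmax(z_imp, z_p) + 0.3
    if (any(bad, na.rm = TRUE))
      warning(sum(bad, na.rm = TRUE),
              " record(s) have p-values inconsistent with |beta/se|")
  }
  list(records = records, n_dropped = n_dropped)
}

#' Read summary statistics from a delimited text file
#'
#' Accepts whitespace- or comma-delimited files with a header row; `.gz`
#' files are decompressed transparently. Alleles are upper-cased and rows
#' failing record invariants are dropped with a logged count.
#'
#' @param path File path.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @inheritParams study_sumstats
#' @return A [study_sumstats()] object.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_name = basename(path),
                          trait_type = c("quantitative", "case_control"),
                          n_cases = NA_integer_, n_controls = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  open(con, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("empty file: ", path)
  sep <- if (grepl(",", first)) "," else ""
  close(con); on.exit(NULL)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  needed <- unlist(dialect[.mandatory_cols])
  missing_cols <- needed[!needed %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  records <- data.frame(variant_id = as.character(raw[[dialect$variant_id]]),
                        chrom = as.character(raw[[dialect$chrom]]),
                        pos = as.integer(raw[[dialect$pos]]),
                        effect_allele = raw[[dialect$effect_allele]],
                        other_allele = raw[[dialect$other_allele]],
                        eaf = if (dialect$eaf %in% names(raw))
                          as.numeric(raw[[dialect$eaf]]) else NA_real_,
                        beta = as.numeric(raw[[dialect$beta]]),
                        se = as.numeric(raw[[dialect$se]]),
                        pvalue = as.numeric(raw[[dialect$pvalue]]),
                        n = if (dialect$n %in% names(raw))
                          as.numeric(raw[[dialect$n]]) else NA_real_,
                        stringsAsFactors = FALSE)
  study_sumstats(records, trait_name = trait_name, trait_type = trait_type,
                 n_cases = n_cases, n_controls = n_controls)
}

#' Write summary statistics to a tab-delimited file
#'
#' Emits the canonical header `SNP CHR POS EA NEA EAF BETA SE P N`.
#' Round-trips bit-exactly with [read_sumstats()] for finite values.
#'
#' @param x A `study_sumstats` object.
#' @param path Output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "study_sumstats"))
  out <- x$records
  names(out) <- c("SNP", "CHR", "POS", "EA", "NEA", "EAF", "BETA", "SE",
                  "P", "N")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# DNA complement for strand resolution; non-ACGT alleles (indels) map to
# NA so they are never complement-resolved.
allele_complement <- function(a) {
  out <- chartr("ACGT", "TGCA", a)
  out[!a %in% c("A", "C", "G", "T")] <- NA_character_
  out
}

is_palindromic <- function(ea, oa) {
  comp <- allele_complement(ea)
  !is.na(comp) & comp == oa
}

#' Harmonize two studies to shared variants with aligned effect alleles
#'
#' Retains variants present in both studies (matched by `variant_id`) and
#' re-expresses study `b`'s effects on study `a`'s effect allele:
#' swapped alleles negate `beta` and reflect `eaf`; strand flips are
#' resolved by complementing; palindromic variants (A/T, C/G) are resolved
#' by allele-frequency concordance and dropped when either frequency lies
#' within `drop_ambiguous_maf` of 0.5 or is missing. Variants whose allele
#' sets are not equal, swapped, or complement-resolvable are dropped.
#'
#' @param a,b `study_sumstats` objects; `a` fixes the output orientation.
#' @param drop_ambiguous_maf Half-width of the ambiguity window around
#'   `eaf = 0.5` for palindromic variants. Default 0.08, i.e. palindromic
#'   variants with `eaf` in (0.42, 0.58) are removed.
#' @return data.frame with one row per retained shared variant:
#'   `variant_id, chrom, pos, effect_allele, other_allele`, then
#'   `eaf_a, beta_a, se_a, pvalue_a, n_a` and the same `_b` columns, all in
#'   `a`'s orientation. Attribute `"log"` carries drop counts
#'   (`n_shared`, `n_flipped`, `n_palindromic_dropped`, `n_incompatible`).
#' @export
harmonize_pair <- function(a, b, drop_ambiguous_maf = 0.08) {
  stopifnot(inherits(a, "study_sumstats"), inherits(b, "study_sumstats"))
  if (nrow(a$records) == 0L || nrow(b$records) == 0L)
    stop("both studies must be non-empty")
  ra <- a$records
  rb <- b$records[match(ra$variant_id, b$records$variant_id), , drop = FALSE]
  shared <- !is.na(rb$variant_id)
  ra <- ra[shared, , drop = FALSE]
  rb <- rb[shared, , drop = FALSE]
  n_shared <- nrow(ra)

  ea_a <- ra$effect_allele; oa_a <- ra$other_allele
  ea_b <- rb$effect_allele; oa_b <- rb$other_allele
  cea_b <- allele_complement(ea_b); coa_b <- allele_complement(oa_b)
  palin <- is_palindromic(ea_a, oa_a)

  same    <- ea_b == ea_a & oa_b == oa_a
  swapped <- ea_b == oa_a & oa_b == ea_a
  c_same  <- !is.na(cea_b) & !is.na(coa_b) & cea_b == ea_a & coa_b == oa_a
  c_swap  <- !is.na(cea_b) & !is.na(coa_b) & cea_b == oa_a & coa_b == ea_a

  # action: 0 keep, 1 flip, NA drop
  action <- rep(NA_real_, n_shared)
  action[same | c_same] <- 0
  action[(swapped | c_swap) & is.na(action)] <- 1

  # Palindromic variants: allele matching cannot fix the strand, so the
  # action is re-derived from frequency concordance.
  if (any(palin)) {
    amb <- palin & (is.na(ra$eaf) | is.na(rb$eaf) |
                      abs(ra$eaf - 0.5) < drop_ambiguous_maf |
                      abs(rb$eaf - 0.5) < drop_ambiguous_maf)
    resolvable <- palin & !amb & !is.na(action)
    action[resolvable] <- ifelse((ra$eaf[resolvable] < 0.5) ==
                                   (rb$eaf[resolvable] < 0.5), 0, 1)
    action[palin & amb] <- NA
  }

  n_palin_dropped <- sum(palin & is.na(action))
  n_incompat <- sum(is.na(action)) - n_palin_dropped

  keep <- !is.na(action)
  ra <- ra[keep, , drop = FALSE]
  rb <- rb[keep, , drop = FALSE]
  act <- action[keep]

  beta_b <- ifelse(act == 1, -rb$beta, rb$beta)
  eaf_b <- ifelse(act == 1, 1 - rb$eaf, rb$eaf)

  out <- data.frame(variant_id = ra$variant_id, chrom = ra$chrom,
                    pos = ra$pos, effect_allele = ra$effect_allele,
                    other_allele = ra$other_allele,
                    eaf_a = ra$eaf, beta_a = ra$beta, se_a = ra$se,
                    pvalue_a = ra$pvalue, n_a = ra$n,
                    eaf_b = eaf_b, beta_b = beta_b, se_b = rb$se,
                    pvalue_b = rb$pvalue, n_b = rb$n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log") <- list(n_shared = n_shared,
                           n_flipped = sum(act == 1),
                           n_palindromic_dropped = n_palin_dropped,
                           n_incompatible = n_incompat)
  out
}
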