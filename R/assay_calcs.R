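#' ChIP-qPCR enrichment as percent of input
#'
#' The input Ct is first adjusted to represent 100% of chromatin
#' (subtracting `log(1/input_fraction, base = efficiency)` cycles, since
#' only a fraction of the chromatin was taken as input), then the
#' enrichment is `100 * efficiency^(adjusted_input_ct - ct_ip)`.
#' Algebraically identical to
#' `100 * input_fraction * efficiency^(ct_input - ct_ip)`.
#'
#' @param ct_input Ct of the input sample (> 0); vectorised.
#' @param ct_ip Ct of the immunoprecipitated sample (> 0).
#' @param input_fraction fraction of chromatin used as input, in (0, 1];
#'   default 0.01 (a 1% input).
#' @param efficiency per-cycle amplification factor, default 2 (perfect
#'   doubling).
#' @return percent-of-input value(s).
#' @export
percent_input <- function(ct_input, ct_ip, input_fraction = 0.01,
                          efficiency = 2) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must lie in (0, 1]")
  if (any(ct_input <= 0) || any(ct_ip <= 0)) stop("Ct values must be > 0")
  if (any(efficiency <= 1)) stop("efficiency must exceed 1")
  adj <- ct_input - log(1 / input_fraction, base = efficiency)
  100 * efficiency^(adj - ct_ip)
}

#' Cumulative cell numbers across passages
#'
#' Cells split at a constant ratio lose `1 - 1/ratio` of the population at
#' each passage; the cumulative cell number corrects the raw count by the
#' expansion the culture would have reached without splitting:
#' `C_i = count_i * prod(ratio_j, j < i)` (the count at passage 0 is
#' uncorrected).
#'
#' @param counts cell counts per passage, in passage order (>= 0).
#' @param split_ratios splitting ratio applied at each passage (>= 1);
#'   length equal to `counts` (the last entry is unused) or a single
#'   constant ratio.
#' @param passages optional passage indices; must be strictly increasing.
#' @return numeric vector of cumulative cell numbers.
#' @export
cumulative_cell_numbers <- function(counts, split_ratios,
                                    passages = NULL) {
  n <- length(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(split_ratios) == 1L) split_ratios <- rep(split_ratios, n)
  if (length(split_ratios) != n)
    stop("split_ratios must be length 1 or length(counts)")
  if (any(split_ratios < 1)) stop("split ratios must be >= 1")
  if (!is.null(passages) && any(diff(passages) <= 0))
    stop("passage indices must be strictly increasing")
  expansion <- c(1, cumprod(split_ratios[-n]))
  counts * expansion
}

#' qPCR primer pair for the MYC promoter-region ChIP amplicon
#'
#' The amplicon used to validate factor binding at the MYC locus by
#' ChIP-qPCR ([percent_input()]).
#'
#' @return named character vector with `forward` and `reverse` 5'->3'
#'   sequences.
#' @export
myc_chip_primers <- function() {
  c(forward = "ACTCACAGGACAAGGATGCG",
    reverse = "TGCTCCTCCGTAGCAGTACT")
}

#' Read a qPCR Ct table and compute percent of input
#'
#' TSV columns: `target`, `ct_input`, `ct_ip`, and optional
#' `input_fraction` (default 0.01).
#'
#' @param path TSV path.
#' @param efficiency per-cycle amplification factor, default 2.
#' @return the table with a `percent_input` column appended.
#' @export
read_qpcr_table <- function(path, efficiency = 2) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "ct_input", "ct_ip")
  if (!all(need %in% names(tab)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  frac <- if ("input_fraction" %in% names(tab)) tab$input_fraction else 0.01
  tab$percent_input <- percent_input(tab$ct_input, tab$ct_ip, frac,
                                     efficiency)
  tab
}
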