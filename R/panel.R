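#' @useDynLib metabscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.LIPID_CLASSES <- c("acylcarnitine", "lysophosphatidylcholine",
                    "phosphatidylcholine", "diglyceride", "triglyceride",
                    "sphingolipid", "cholesteryl_ester")

.ALL_CLASSES <- c("amino_acid", "biogenic_amine", .LIPID_CLASSES, "hexose")

# systematic CLASS(C:D) ids; `named` entries come first and are guaranteed in
.systematicIds <- function(prefix, named, n, carbons, doubles) {
  grid <- expand.grid(d = doubles, c = carbons)
  ids <- sprintf("%s(%d:%d)", prefix, grid$c, grid$d)
  ids <- c(named, setdiff(ids, named))
  if (length(ids) < n)
    stop("id grid for ", prefix, " too small")
  ids[seq_len(n)]
}

#' Default analyte panel registry
#'
#' Builds the registry of the 408-analyte targeted serum panel used throughout
#' the package: 21 amino acids + 21 biogenic amines, 55 acylcarnitines,
#' 15 diglycerides + 45 triglycerides, 24 lysophosphatidylcholines +
#' 172 phosphatidylcholines, 40 sphingolipids, 14 cholesteryl esters and one
#' hexose. The seven lipid classes are flagged \code{is_lipid}. Analyte ids use
#' the field's \code{CLASS(C:D)} notation (carbons:double bonds); compounds
#' referenced by name in downstream defaults (e.g. \code{LPC(18:0)},
#' \code{CE(20:5)}) are present verbatim.
#'
#' The per-class counts sum to 408; the kit's headline count of 407 "metabolites
#' or their isomer groups" differs by one from the sum of its own per-class
#' enumeration, and the registry follows the finer-grained per-class counts.
#'
#' @return A \code{data.frame} with columns \code{analyte_id},
#'   \code{analyte_class} and \code{is_lipid}, one row per analyte, in a fixed
#'   deterministic order.
#' @examples
#' panel <- defaultPanel()
#' table(panel$analyte_class)
#' @export
defaultPanel <- function() {
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr",
          "Trp", "Tyr", "Val")
  amine <- c("ADMA", "SDMA", "alpha-AAA", "Ac-Orn", "Betaine", "Carnosine",
             "Creatinine", "DOPA", "Dopamine", "Histamine", "Kynurenine",
             "Met-SO", "Nitro-Tyr", "PEA", "Putrescine", "Sarcosine",
             "Serotonin", "Spermidine", "Spermine", "Taurine", "t4-OH-Pro")
  ac  <- .systematicIds("AC",  character(0), 55, carbons = 0:26, doubles = 0:2)
  dg  <- .systematicIds("DG",  "DG(39:0)",   15, carbons = 32:46, doubles = 0:2)
  tg  <- .systematicIds("TG",  "TG(52:4)",   45, carbons = 44:58, doubles = 0:5)
  lpc <- .systematicIds("LPC", "LPC(18:0)",  24, carbons = 14:26, doubles = 0:2)
  pc  <- .systematicIds("PC",  c("PC(32:3)", "PC(41:5)", "PC(38:6)", "PC(40:6)"),
                        172, carbons = 24:49, doubles = 0:7)
  sm  <- .systematicIds("SM",  "SM(38:1)",   40, carbons = 30:43, doubles = 0:2)
  ce  <- .systematicIds("CE",  "CE(20:5)",   14, carbons = 14:20, doubles = 0:6)

  cls <- rep(.ALL_CLASSES,
             times = c(21, 21, 55, 24, 172, 15, 45, 40, 14, 1))
  ids <- c(aa, amine, ac, lpc, pc, dg, tg, sm, ce, "H1")
  stopifnot(!anyDuplicated(ids), length(ids) == 408)
  data.frame(analyte_id = ids,
             analyte_class = cls,
             is_lipid = cls %in% .LIPID_CLASSES,
             stringsAsFactors = FALSE)
}

#' Lipid classes of the panel
#'
#' @return Character vector of the seven lipid class labels.
#' @export
lipidClasses <- function() .LIPID_CLASSES
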