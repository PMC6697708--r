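# shared internal helpers: error classes, residue-name tables, geometry

dh_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("dhprof_", class), "dhprof_error"), ...)
}

# 3-letter -> 1-letter codes for the 20 standard amino acids
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))
.aa_letters <- sort(unname(.aa3to1))

aa_three_to_one <- function(resname, mse_as_met = FALSE) {
  out <- unname(.aa3to1[resname])
  if (mse_as_met) out[resname == "MSE"] <- "M"
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(letters1) {
  out <- unname(.aa1to3[letters1])
  out[is.na(out)] <- "UNK"
  out
}

vec_norm <- function(v) sqrt(sum(v^2))

# contiguous runs of a sorted integer vector -> tibble(start, end, length)
runs_from_numbers <- function(x) {
  x <- sort(unique(as.integer(x)))
  if (length(x) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), length = integer()))
  }
  brk <- c(0L, which(diff(x) != 1L), length(x))
  tibble::tibble(
    start = x[head(brk, -1L) + 1L],
    end = x[brk[-1L]]
  ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)
}

# evaluate expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}
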