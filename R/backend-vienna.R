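# ViennaRNA command-line backend. Sequences are folded in batch through one
# RNAfold / RNAcofold process; structures and energies are parsed from the
# text output. Pair folding defaults to 25 degrees C with the 1999 Turner
# parameter set bundled with ViennaRNA.

vienna_available <- function() {
  nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAcofold"))
}

# Resolve a parameter-set name ("turner1999", "turner2004", ...) or file
# path to a .par file; NULL keeps the program's built-in defaults.
vienna_param_file <- function(parameters) {
  if (is.null(parameters)) return(NULL)
  if (file.exists(parameters)) return(normalizePath(parameters))
  fname <- if (stringr::str_detect(parameters, "\\.par$")) parameters
    else paste0("rna_", parameters, ".par")
  prefix <- dirname(dirname(Sys.which("RNAfold")))
  cand <- file.path(prefix, "share", "ViennaRNA", fname)
  if (file.exists(cand)) return(cand)
  abort(sprintf("cannot resolve ViennaRNA parameter set '%s'", parameters))
}

vienna_run <- function(program, sequences, temperature, parameters) {
  if (!vienna_available()) {
    abort("ViennaRNA executables not found on PATH; use the 'toy' engine")
  }
  args <- c("--noPS", "-T", format(temperature))
  pfile <- vienna_param_file(parameters)
  if (!is.null(pfile)) args <- c(args, "-P", pfile)
  ids <- paste0("s", seq_along(sequences))
  input <- as.vector(rbind(paste0(">", ids), sequences))
  out <- withr::with_tempdir(
    system2(program, args, input = input, stdout = TRUE, stderr = FALSE)
  )
  headers <- which(stringr::str_starts(out, ">"))
  if (length(headers) != length(sequences)) {
    abort(sprintf("%s returned %d records for %d sequences",
                  program, length(headers), length(sequences)))
  }
  struct_lines <- out[headers + 2]
  m <- stringr::str_match(struct_lines,
                          "^([.()&]+)\\s+\\(\\s*(-?\\d+(?:\\.\\d+)?)\\s*\\)")
  if (anyNA(m[, 1])) {
    abort(sprintf("could not parse %s output line: '%s'",
                  program, struct_lines[which(is.na(m[, 1]))[1]]))
  }
  tibble(structure = m[, 2], mfe = as.numeric(m[, 3]))
}

vienna_fold_batch <- function(sequences, temperature = 37, parameters = NULL) {
  vienna_run("RNAfold", sequences, temperature, parameters)
}

vienna_cofold_batch <- function(a, b, temperature = 25,
                                parameters = "turner1999") {
  vienna_run("RNAcofold", paste0(a, "&", b), temperature, parameters)
}
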