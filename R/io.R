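#' Detect the on-disk dialect of a model file
#'
#' Detection is deterministic: the file extension proposes a dialect
#' (`.json` is COBRA JSON, `.xml` / `.sbml` is SBML fbc, `.mat` is the
#' COBRA Toolbox MATLAB dialect) and content sniffing — a leading `{`
#' versus `<?xml` — overrides it.
#'
#' @param path Path to an existing model file.
#' @return One of `"cobra_json"`, `"sbml_fbc"`, `"cobra_mat"`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", sQuote(path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  by_ext <- switch(ext, json = "cobra_json", xml = , sbml = "sbml_fbc",
                   mat = "cobra_mat", NA_character_)
  head_raw <- readBin(path, "raw", n = 256L)
  txt <- trimws(rawToChar(head_raw[head_raw != as.raw(0)]))
  by_content <- if (startsWith(txt, "{")) "cobra_json"
                else if (startsWith(txt, "<")) "sbml_fbc"
                else if (startsWith(txt, "MATLAB")) "cobra_mat"
                else NA_character_
  fmt <- by_content %na% by_ext
  if (is.na(fmt)) {
    stop("cannot detect model dialect of ", sQuote(path),
         "; supported: cobra_json (.json), sbml_fbc (.xml/.sbml), ",
         "cobra_mat (.mat)", call. = FALSE)
  }
  fmt
}

#' Read a model, auto-detecting its dialect
#'
#' Dispatches on [detect_format()] to [read_model_json()] or
#' [read_model_sbml()]. The COBRA MATLAB dialect is detected but not
#' readable by this package.
#'
#' @param path Path to the model file.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path) {
  switch(detect_format(path),
    cobra_json = read_model_json(path),
    sbml_fbc = read_model_sbml(path),
    cobra_mat = stop("the COBRA MATLAB dialect is detected but not ",
                     "supported; convert the model to COBRA JSON or SBML ",
                     "fbc first", call. = FALSE)
  )
}
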