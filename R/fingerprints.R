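#' Molecular fingerprints and metabolite distances
#'
#' Metabolite prior knowledge enters the model as a pairwise distance matrix
#' computed from molecular fingerprints. Five fingerprint methods are
#' recognised: `cactvs` (881-bit substructure keys decoded from cached
#' PubChem records), `morgan` (2048-bit extended-connectivity), `mqn`
#' (42 structural-feature counts), `map4` (1024-dimension MinHashed
#' atom-pair), and `infomax` (pretrained graph encoder; optional backend,
#' not bundled). Binary fingerprints are compared with the Tanimoto/Jaccard
#' distance, MQN with the city-block distance, and MAP4 with one minus the
#' fraction of matching MinHash components.
#'
#' @name fingerprints
NULL

fp_lengths <- c(cactvs = 881L, morgan = 2048L, mqn = 42L, map4 = 1024L,
                infomax = 300L)

#' @rdname fingerprints
#' @param method fingerprint method name.
#' @return `fingerprint_length()` returns the fixed vector length of a method.
#' @export
fingerprint_length <- function(method) {
  method <- match.arg(method, names(fp_lengths))
  fp_lengths[[method]]
}

new_fingerprint <- function(vector, method) {
  method <- match.arg(method, names(fp_lengths))
  if (length(vector) != fp_lengths[[method]]) {
    stop(sprintf("%s fingerprint must have length %d, got %d",
                 method, fp_lengths[[method]], length(vector)))
  }
  is_binary <- method %in% c("cactvs", "morgan")
  if (is_binary && !all(vector %in% c(0, 1))) {
    stop("binary fingerprint contains values outside {0,1}")
  }
  if (method == "mqn" && (any(vector < 0) || any(vector != round(vector)))) {
    stop("mqn fingerprint must contain non-negative integer counts")
  }
  structure(list(vector = as.numeric(vector), method = method,
                 is_binary = is_binary), class = "fingerprint")
}

# ---- RDKit bridge ---------------------------------------------------------

bridge_script <- function() {
  p <- system.file("python", "chem_bridge.py", package = "mmrules")
  if (p == "") p <- file.path("inst", "python", "chem_bridge.py")
  p
}

rdkit_available <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import rdkit")), stdout = FALSE,
            stderr = FALSE) == 0
}

call_rdkit <- function(structures, what) {
  if (!rdkit_available()) {
    stop("rdkit backend unavailable: the system python with rdkit is needed ",
         "for '", what, "'")
  }
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(list(what = what, structures = as.list(structures)),
                       infile, auto_unbox = TRUE, null = "null")
  status <- system2("python", c(bridge_script(), infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile)) {
    stop("rdkit bridge failed for request '", what, "'")
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# ---- Structure resolution -------------------------------------------------

#' Resolve metabolite identifiers to structures
#'
#' InChI and SMILES identifiers are parsed directly. Database accessions
#' (HMDB, KEGG, PubChem CID, InChIKey) are looked up in a local cache
#' directory of previously fetched records; with no cache hit the metabolite
#' is flagged unresolved and later excluded from distance computation with a
#' warning (partial identifier coverage is the norm in metabolomics).
#'
#' @param ids tibble with columns `feature_id`, `id_type` (one of `HMDB`,
#'   `KEGG`, `InChI`, `InChIKey`, `PubChemCID`, `SMILES`), `id_value`.
#' @param cache_dir optional directory of cached records: one JSON file per
#'   accession (named `<id_value>.json`) with fields `smiles` and optionally
#'   `cactvs_base64` (the provider's base64-encoded 881-bit fingerprint).
#' @return the input tibble with added columns `structure` (canonical
#'   SMILES or `NA`), `cactvs_base64` (`NA` unless cached), and `resolved`.
#' @export
resolve_structures <- function(ids, cache_dir = NULL) {
  stopifnot(all(c("feature_id", "id_type", "id_value") %in% names(ids)))
  ids <- tibble::as_tibble(ids)
  raw_structure <- ifelse(ids$id_type %in% c("InChI", "SMILES"),
                          ids$id_value, NA_character_)
  # InChI is converted to SMILES with OpenBabel (the bundled RDKit parses
  # SMILES reliably but not InChI)
  is_inchi <- which(ids$id_type == "InChI")
  if (length(is_inchi) > 0) {
    raw_structure[is_inchi] <- inchi_to_smiles(ids$id_value[is_inchi])
  }
  cactvs64 <- rep(NA_character_, nrow(ids))
  needs_cache <- which(is.na(raw_structure))
  for (i in needs_cache) {
    if (is.null(cache_dir)) next
    f <- file.path(cache_dir, paste0(ids$id_value[i], ".json"))
    if (file.exists(f)) {
      rec <- jsonlite::read_json(f)
      if (!is.null(rec$smiles)) raw_structure[i] <- rec$smiles
      if (!is.null(rec$cactvs_base64)) cactvs64[i] <- rec$cactvs_base64
    }
  }
  structure_out <- rep(NA_character_, nrow(ids))
  have <- which(!is.na(raw_structure))
  if (length(have) > 0) {
    canon <- call_rdkit(raw_structure[have], "canonical")
    structure_out[have] <- vapply(canon, function(x) {
      if (is.null(x)) NA_character_ else x
    }, character(1))
  }
  resolved <- !is.na(structure_out) | !is.na(cactvs64)
  if (any(!resolved)) {
    warning(sum(!resolved), " metabolite(s) unresolved: ",
            paste(utils::head(ids$feature_id[!resolved], 5), collapse = ", "))
  }
  dplyr::mutate(ids, structure = structure_out, cactvs_base64 = cactvs64,
                resolved = resolved)
}

# InChI -> SMILES via the OpenBabel CLI; NA where conversion fails
inchi_to_smiles <- function(inchi) {
  if (!nzchar(Sys.which("obabel"))) return(rep(NA_character_, length(inchi)))
  vapply(inchi, function(x) {
    infile <- tempfile(fileext = ".inchi")
    writeLines(x, infile)
    on.exit(unlink(infile), add = TRUE)
    out <- suppressWarnings(system2("obabel",
                                    c("-iinchi", infile, "-osmi"),
                                    stdout = TRUE, stderr = FALSE))
    smi <- trimws(out[nzchar(trimws(out))])
    if (length(smi) == 0) NA_character_ else strsplit(smi[1], "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

# ---- Fingerprint computation ---------------------------------------------

#' Compute one molecular fingerprint
#'
#' @param structure canonical SMILES or InChI string; for `cactvs`, the
#'   base64-encoded PubChem fingerprint record instead (decoded, never
#'   recomputed locally).
#' @param method one of `cactvs`, `morgan`, `mqn`, `map4`, `infomax`.
#' @return a `fingerprint` object (fields `vector`, `method`, `is_binary`).
#' @export
compute_fingerprint <- function(structure, method = c("cactvs", "morgan",
                                                      "mqn", "map4",
                                                      "infomax")) {
  method <- match.arg(method)
  if (is.null(structure) || is.na(structure) || !nzchar(structure)) {
    stop("empty structure string")
  }
  if (method == "infomax") {
    stop("backend unavailable: the infomax fingerprint needs a pretrained ",
         "graph encoder that is not bundled")
  }
  if (method == "cactvs") {
    return(new_fingerprint(decode_cactvs(structure), "cactvs"))
  }
  if (startsWith(structure, "InChI=")) {
    structure <- inchi_to_smiles(structure)
    if (is.na(structure)) stop("unparsable InChI")
  }
  res <- call_rdkit(structure, method_request(method))[[1]]
  if (is.null(res)) stop("unparsable structure: ", structure)
  if (method == "map4") {
    return(new_fingerprint(minhash_shingles(unlist(res), 1024L), "map4"))
  }
  new_fingerprint(unlist(res), method)
}

method_request <- function(method) {
  switch(method, morgan = "morgan", mqn = "mqn", map4 = "shingles")
}

#' Decode / encode PubChem-format CACTVS fingerprints
#'
#' PubChem distributes the 881-bit CACTVS substructure fingerprint as base64
#' text: a 4-byte big-endian bit-length prefix followed by the packed bits
#' (MSB first). `decode_cactvs()` unpacks it to a 0/1 vector of length 881;
#' `encode_cactvs()` is its inverse, used to build offline caches and test
#' fixtures.
#'
#' @param b64 base64 string.
#' @return integer vector of 881 bits.
#' @export
decode_cactvs <- function(b64) {
  bytes <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (length(bytes) < 4) stop("truncated cactvs record")
  nbits <- sum(as.integer(bytes[1:4]) * 256^(3:0))
  if (nbits != 881) stop("cactvs record declares ", nbits, " bits, not 881")
  bits <- as.integer(rawToBits(bytes[-(1:4)]))
  # rawToBits is LSB-first per byte; PubChem packs MSB-first
  bits <- as.vector(matrix(bits, nrow = 8)[8:1, ])
  bits[seq_len(881)]
}

#' @rdname decode_cactvs
#' @param bits 0/1 vector of length 881.
#' @export
encode_cactvs <- function(bits) {
  stopifnot(length(bits) == 881, all(bits %in% c(0, 1)))
  padded <- c(as.integer(bits), integer(8 * ceiling(881 / 8) - 881))
  msb <- matrix(padded, nrow = 8)[8:1, ]
  bytes <- packBits(as.integer(as.vector(msb)), type = "raw")
  header <- as.raw(c(0, 0, 881 %/% 256, 881 %% 256))
  jsonlite::base64_enc(c(header, bytes))
}

# MinHash of a shingle set: 1024 independent affine hash functions over a
# 31-bit polynomial string hash, all in double arithmetic (< 2^53, exact).
minhash_shingles <- function(shingles, n_perm = 1024L) {
  prime <- 2147483647  # 2^31 - 1
  # fixed (a, b) coefficients derived from a deterministic LCG so the
  # fingerprint is reproducible across sessions without touching .Random.seed
  lcg <- function(n, seed) {
    out <- numeric(n)
    x <- seed
    for (i in seq_len(n)) {
      x <- (1103515245 * x + 12345) %% prime
      out[i] <- x
    }
    out
  }
  a <- lcg(n_perm, 42) %% (prime - 1) + 1
  b <- lcg(n_perm, 2026) %% prime
  if (length(shingles) == 0) return(rep(prime, n_perm))
  base_hash <- vapply(shingles, function(s) {
    h <- 0
    for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% prime
    h
  }, numeric(1), USE.NAMES = FALSE)
  out <- rep(Inf, n_perm)
  for (h in base_hash) {
    out <- pmin(out, (a * h + b) %% prime)
  }
  out
}

# ---- Distances ------------------------------------------------------------

#' Tanimoto (Jaccard) distance between binary fingerprints
#'
#' One minus intersection over union of the on-bits. Two all-zero vectors
#' are at distance 0; an all-zero vector is at distance 1 from any nonzero
#' vector.
#'
#' @param a,b `fingerprint` objects of the same binary method, or plain 0/1
#'   vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  va <- fp_vec(a, binary = TRUE); vb <- fp_vec(b, binary = TRUE)
  check_same_method(a, b)
  if (length(va) != length(vb)) stop("fingerprint length mismatch")
  un <- sum(va | vb)
  if (un == 0) return(0)
  1 - sum(va & vb) / un
}

#' City-block (L1) distance between count fingerprints
#'
#' @param a,b `fingerprint` objects (method `mqn`) or plain numeric vectors.
#' @return non-negative distance.
#' @export
cityblock_distance <- function(a, b) {
  va <- fp_vec(a); vb <- fp_vec(b)
  check_same_method(a, b)
  if (length(va) != length(vb)) stop("fingerprint length mismatch")
  sum(abs(va - vb))
}

map4_distance <- function(a, b) {
  va <- fp_vec(a); vb <- fp_vec(b)
  1 - mean(va == vb)
}

fp_vec <- function(x, binary = FALSE) {
  v <- if (inherits(x, "fingerprint")) {
    if (binary && !x$is_binary) stop("binary fingerprint required")
    x$vector
  } else {
    as.numeric(x)
  }
  if (binary && !all(v %in% c(0, 1))) stop("binary fingerprint required")
  v
}

check_same_method <- function(a, b) {
  if (inherits(a, "fingerprint") && inherits(b, "fingerprint") &&
      a$method != b$method) {
    stop("fingerprint method mismatch: ", a$method, " vs ", b$method)
  }
}

#' Build the metabolite pairwise distance matrix
#'
#' Computes fingerprints for every resolved metabolite and assembles the
#' symmetric distance matrix with the method's metric (Tanimoto for
#' `cactvs`/`morgan`, city-block for `mqn`, one-minus-MinHash-agreement for
#' `map4`). Unresolved metabolites are dropped with a warning.
#'
#' @param ids output of [resolve_structures()] (or a tibble with columns
#'   `feature_id`, `structure`, optionally `cactvs_base64`, `resolved`).
#' @param method fingerprint method.
#' @return a [dist_matrix()] over the resolved metabolites.
#' @export
build_metabolite_distances <- function(ids, method = "cactvs") {
  method <- match.arg(method, names(fp_lengths))
  if (!"resolved" %in% names(ids)) ids$resolved <- !is.na(ids$structure)
  if (method == "cactvs") {
    ids$resolved <- ids$resolved & !is.na(ids$cactvs_base64)
  }
  kept <- ids[ids$resolved, , drop = FALSE]
  if (sum(ids$resolved) < nrow(ids)) {
    warning("excluding ", nrow(ids) - sum(ids$resolved),
            " unresolved metabolite(s) from the distance matrix")
  }
  if (nrow(kept) < 2) stop("need at least 2 resolved metabolites")
  fps <- if (method == "cactvs") {
    lapply(kept$cactvs_base64, compute_fingerprint, method = "cactvs")
  } else if (method == "map4") {
    sh <- call_rdkit(kept$structure, "shingles")
    lapply(sh, function(s) {
      if (is.null(s)) stop("unparsable structure during fingerprinting")
      new_fingerprint(minhash_shingles(unlist(s), 1024L), "map4")
    })
  } else {
    res <- call_rdkit(kept$structure, method_request(method))
    lapply(res, function(v) {
      if (is.null(v)) stop("unparsable structure during fingerprinting")
      new_fingerprint(unlist(v), method)
    })
  }
  n <- length(fps)
  D <- matrix(0, n, n, dimnames = list(kept$feature_id, kept$feature_id))
  metric <- switch(method, cactvs = tanimoto_distance,
                   morgan = tanimoto_distance, mqn = cityblock_distance,
                   map4 = map4_distance)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- metric(fps[[i]], fps[[j]])
    }
  }
  dist_matrix(D)
}

#' Read a precomputed metabolite distance or similarity table
#'
#' @param path square CSV with matching row/column labels.
#' @param similarities if `TRUE` values are similarities and are converted
#'   via `1 - s` (clipped to `[0, 1]`).
#' @return a [dist_matrix()].
#' @export
read_metabolite_distances <- function(path, similarities = FALSE) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (similarities) m <- pmin(pmax(1 - m, 0), 1)
  dist_matrix(m[, rownames(m), drop = FALSE])
}
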