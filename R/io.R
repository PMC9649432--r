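# Atomic file writes: produce the file under a temporary name in the
# destination directory, then rename. A crash never leaves a partial
# file that parses as complete.
.atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path),
                  fileext = paste0(".tmp.", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file onto ", path, call. = FALSE)
  }
  invisible(path)
}

.write_json_atomic <- function(x, path) {
  .atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
}

.write_nifti_atomic <- function(img, path, datatype = "auto") {
  .atomic_write(path, function(tmp) {
    RNifti::writeNifti(img, tmp, datatype = datatype)
  })
}

#' Write a multi-echo acquisition as a NIfTI pair plus JSON sidecar
#'
#' Complex data are stored as two 3-D volumes (echo along the third
#' axis): `<stem>_real.nii.gz` and `<stem>_imag.nii.gz`, with the
#' protocol in `<stem>.json` (`echo_times_ms`, `fat_shift_hz`,
#' `noise_sd`, `name`). Writes are atomic.
#'
#' @param image An `hf_multiecho`.
#' @param path_stem Path prefix without suffix.
#' @return The stem, invisibly.
#' @export
write_multiecho <- function(image, path_stem) {
  stopifnot(inherits(image, "hf_multiecho"))
  .write_nifti_atomic(Re(image$data), paste0(path_stem, "_real.nii.gz"))
  .write_nifti_atomic(Im(image$data), paste0(path_stem, "_imag.nii.gz"))
  p <- image$protocol
  .write_json_atomic(
    list(echo_times_ms = p$echo_times_ms, fat_shift_hz = p$fat_shift_hz,
         noise_sd = p$noise_sd, name = p$name),
    paste0(path_stem, ".json"))
  invisible(path_stem)
}

#' Read a multi-echo acquisition written by [write_multiecho()]
#'
#' @param path_stem Path prefix of the `_real`/`_imag`/`.json` triple.
#' @return An `hf_multiecho` (without embedded ground truth).
#' @export
read_multiecho <- function(path_stem) {
  paths <- paste0(path_stem, c("_real.nii.gz", "_imag.nii.gz", ".json"))
  for (p in paths) {
    if (!file.exists(p)) stop("missing component: ", p, call. = FALSE)
  }
  re <- as.array(RNifti::readNifti(paths[1]))
  im <- as.array(RNifti::readNifti(paths[2]))
  if (!identical(dim(re), dim(im))) {
    stop("real/imaginary volumes disagree in shape", call. = FALSE)
  }
  side <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  req <- c("echo_times_ms", "fat_shift_hz", "noise_sd", "name")
  if (!all(req %in% names(side))) {
    stop("sidecar missing fields: ",
         paste(setdiff(req, names(side)), collapse = ", "), call. = FALSE)
  }
  if (length(dim(re)) != 3L ||
      dim(re)[3] != length(side$echo_times_ms)) {
    stop(sprintf("sidecar lists %d echo times but volumes carry %d echoes",
                 length(side$echo_times_ms),
                 if (length(dim(re)) == 3L) dim(re)[3] else NA_integer_),
         call. = FALSE)
  }
  protocol <- hf_protocol(side$echo_times_ms, side$fat_shift_hz,
                          side$noise_sd, side$name)
  structure(list(data = array(complex(real = re, imaginary = im),
                              dim(re)),
                 protocol = protocol, truth = NULL),
            class = "hf_multiecho")
}

#' Write ground-truth parameter maps as one NIfTI per map
#'
#' @param maps An `hf_parameter_maps`.
#' @param path_stem Path prefix; writes `<stem>_<map>.nii.gz` for rho_w,
#'   rho_f, field_map, r2star, and the mask as uint8.
#' @return The stem, invisibly.
#' @export
write_parameter_maps <- function(maps, path_stem) {
  stopifnot(inherits(maps, "hf_parameter_maps"))
  for (nm in c("rho_w", "rho_f", "field_map", "r2star")) {
    .write_nifti_atomic(maps[[nm]], paste0(path_stem, "_", nm, ".nii.gz"))
  }
  .write_nifti_atomic(maps$mask + 0L, paste0(path_stem, "_mask.nii.gz"),
                      datatype = "uint8")
  invisible(path_stem)
}

#' Read parameter maps written by [write_parameter_maps()]
#'
#' @param path_stem Path prefix.
#' @return An `hf_parameter_maps`.
#' @export
read_parameter_maps <- function(path_stem) {
  rd <- function(nm) {
    p <- paste0(path_stem, "_", nm, ".nii.gz")
    if (!file.exists(p)) stop("missing component: ", p, call. = FALSE)
    m <- as.array(RNifti::readNifti(p))
    dim(m) <- dim(m)[1:2]
    m
  }
  parameter_maps(rd("rho_w"), rd("rho_f"), rd("field_map"), rd("r2star"),
                 rd("mask") > 0)
}

#' Write a fitted PDFF map (and R2* when present)
#'
#' @param pdff_map An `hf_pdff_map`.
#' @param path_stem Path prefix; writes `<stem>_pdff.nii.gz` and, for
#'   IDEAL fits, `<stem>_r2star.nii.gz`.
#' @return The stem, invisibly.
#' @export
write_pdff_map <- function(pdff_map, path_stem) {
  stopifnot(inherits(pdff_map, "hf_pdff_map"))
  .write_nifti_atomic(pdff_map$pdff, paste0(path_stem, "_pdff.nii.gz"))
  if (!is.null(pdff_map$r2star)) {
    .write_nifti_atomic(pdff_map$r2star,
                        paste0(path_stem, "_r2star.nii.gz"))
  }
  invisible(path_stem)
}

#' Write a cohort as phenotype + genotype TSV files
#'
#' `<dir>/phenotypes.tsv` holds sample_id, covariates, traits and
#' diagnoses; `<dir>/genotypes.tsv` holds sample_id plus one 0/1/2
#' column per variant. Tab-separated, header row, UTF-8.
#'
#' @param cohort An `hf_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hf_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pheno <- cbind(cohort$covariates, cohort$traits, cohort$diagnoses)
  .atomic_write(file.path(dir, "phenotypes.tsv"), function(tmp) {
    utils::write.table(pheno, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  geno <- data.frame(sample_id = cohort$covariates$sample_id,
                     cohort$genotypes, check.names = FALSE)
  .atomic_write(file.path(dir, "genotypes.tsv"), function(tmp) {
    utils::write.table(geno, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(dir)
}

#' Read a cohort from TSV files written by [write_cohort()]
#'
#' Validates genotype values (0/1/2 or NA), sample-id uniqueness and
#' agreement between the two tables. Comma-separated files are accepted.
#'
#' @param dir Directory holding `phenotypes.tsv` and `genotypes.tsv`.
#' @return An `hf_cohort` (without the generator's `mafs`; empirical
#'   frequencies are recomputed).
#' @export
read_cohort <- function(dir) {
  read_tab <- function(p) {
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    first <- readLines(p, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  pheno <- read_tab(file.path(dir, "phenotypes.tsv"))
  geno <- read_tab(file.path(dir, "genotypes.tsv"))
  if (anyDuplicated(pheno$sample_id)) {
    stop("duplicated sample id in phenotypes: ",
         pheno$sample_id[duplicated(pheno$sample_id)][1], call. = FALSE)
  }
  if (!identical(sort(pheno$sample_id), sort(geno$sample_id))) {
    stop("sample ids differ between phenotype and genotype tables",
         call. = FALSE)
  }
  geno <- geno[match(pheno$sample_id, geno$sample_id), , drop = FALSE]
  G <- as.matrix(geno[, setdiff(names(geno), "sample_id"), drop = FALSE])
  bad <- !(G %in% c(0L, 1L, 2L) | is.na(G))
  if (any(bad)) {
    stop("malformed genotype value(s): ",
         paste(utils::head(unique(G[bad]), 3), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(G) <- "integer"
  rownames(G) <- NULL
  cov_cols <- intersect(c("sample_id", "sex", "age", "year_of_birth",
                          "bmi"), names(pheno))
  diag_cols <- names(pheno)[vapply(pheno, is.logical, TRUE)]
  trait_cols <- setdiff(names(pheno), c(cov_cols, diag_cols))
  structure(
    list(genotypes = G,
         mafs = colMeans(G, na.rm = TRUE) / 2,
         covariates = pheno[, cov_cols, drop = FALSE],
         traits = pheno[, trait_cols, drop = FALSE],
         diagnoses = pheno[, diag_cols, drop = FALSE]),
    class = "hf_cohort"
  )
}

#' Read genotypes from a minimal VCF
#'
#' Parses the GT field of a diploid VCF into allele counts: `0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> NA. Phasing separators
#' (`|`) are accepted; phasing semantics are ignored.
#'
#' @param path VCF path (plain or bgzipped).
#' @return Integer matrix samples x variants, variant ids as column
#'   names, plus attribute `"alt_alleles"` naming the counted allele.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  })
  G <- t(counts)
  ids <- v@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(v@fix[noid, "CHROM"], ":", v@fix[noid, "POS"])
  colnames(G) <- ids
  attr(G, "alt_alleles") <- stats::setNames(v@fix[, "ALT"], ids)
  G
}

#' Write a protein panel as TSV
#'
#' @param panel An `hf_protein_panel`.
#' @param path Output TSV path (sample_id, label, one column per
#'   analyte).
#' @return `path`, invisibly.
#' @export
write_protein_panel <- function(panel, path) {
  stopifnot(inherits(panel, "hf_protein_panel"))
  df <- data.frame(sample_id = sprintf("S%05d", seq_len(nrow(panel$levels))),
                   label = panel$labels, panel$levels, check.names = FALSE)
  .atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}

#' Read a protein panel TSV written by [write_protein_panel()]
#'
#' @param path TSV path.
#' @return An `hf_protein_panel` (with empty `informative_ids`).
#' @export
read_protein_panel <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  lv <- as.matrix(df[, setdiff(names(df), c("sample_id", "label")),
                     drop = FALSE])
  structure(list(levels = lv, informative_ids = character(0),
                 labels = as.logical(df$label)),
            class = "hf_protein_panel")
}
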