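## Small plain-text fixture writers used by the I/O tests. Everything is
## generated at test time; nothing binary is stored in the repository.

writeToyMaf <- function(df, file = tempfile(fileext = ".maf")) {
    ## df: sample, chrom, start, end, class
    out <- data.frame(
        Tumor_Sample_Barcode = df$sample,
        Chromosome = df$chrom,
        Start_Position = df$start,
        End_Position = df$end,
        Variant_Classification = df$class
    )
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file
}

## minimal VCF 4.2 with a GT FORMAT field and an AF INFO field
writeToyVcf <- function(file = tempfile(fileext = ".vcf"),
                        samples = "S1",
                        records = data.frame(
                            chrom = c("chr1", "chr1"),
                            pos = c(5L, 100L),
                            ref = c("A", "ACGT"),
                            alt = c("T", "A"),
                            af = c(0.1, 0.25))) {
    gts <- matrix("0/1", nrow(records), length(samples))
    lines <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chr1,length=10000>",
        "##contig=<ID=chr2,length=10000>",
        '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele Frequency">',
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t")
    )
    for (r in seq_len(nrow(records))) {
        lines <- c(lines, paste(c(
            records$chrom[r], records$pos[r], ".", records$ref[r],
            records$alt[r], ".", "PASS",
            sprintf("AF=%s", records$af[r]), "GT", gts[r, ]),
            collapse = "\t"))
    }
    writeLines(lines, file)
    file
}

writeToyBed <- function(lines, file = tempfile(fileext = ".bed")) {
    writeLines(lines, file)
    file
}

writeToyGff3 <- function(file = tempfile(fileext = ".gff3"),
                         genes = data.frame(
                             chrom = c("chr1", "chr1"),
                             start = c(100L, 500L),
                             end = c(200L, 700L),
                             name = c("GENE1", "GENE2"))) {
    lines <- c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=g%d;Name=%s",
                       genes$chrom, genes$start, genes$end,
                       seq_len(nrow(genes)), genes$name))
    writeLines(lines, file)
    file
}
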