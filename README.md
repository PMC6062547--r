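# sulfenpred

Sequence-based prediction of protein **S-sulfenylation** sites.

S-sulfenylation — the reversible, mostly H₂O₂-driven oxidation of a cysteine
free thiol (-SH) to sulfenic acid (-SOH) — is a redox-regulatory
post-translational modification. Mapping it experimentally requires
chemoselective labelling plus tandem MS, so sequence-based predictors are
the practical complement for prioritising candidate cysteines. `sulfenpred`
is for computational biologists who have a FASTA file and a table of
labelled cysteine sites (or no data at all — a synthetic generator is
included) and want a trainable, evaluable predictor with an honest
evaluation protocol.

## Method

Each candidate cysteine is represented by a 21-residue window (10 flanking
residues per side, X-padded past protein termini) and encoded into five
feature blocks, concatenated in fixed order:

| Block   | Encoding                                               | Dim |
|---------|--------------------------------------------------------|-----|
| BE      | one-hot per flanking position, 21-letter alphabet      | 420 |
| AAindex | 14 physicochemical property scales per position        | 280 |
| KSAAP   | ordered residue-pair counts at spacings k ∈ {0, 1, 2}  | 1,323 |
| AAC     | composition F_a = R_a / R over the 20 flank positions  | 20  |
| HQI     | 8 high-quality AAindex indices per position            | 160 |

for 2,203 features in total. Training data are balanced by seeded random
oversampling of the minority class (every original row kept; minority rows
replicated uniformly at random), then fed to an RBF-kernel SVM
(`exp(-γ‖u−v‖²)`, C = 0.1, γ = 0.005 by default). Evaluation reports
ACC/SN/SP (per cent), the Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

and a tie-grouped ROC curve whose trapezoid AUC equals the Mann–Whitney U
statistic. `cross_validate()` does stratified 10-fold CV and exposes *where*
oversampling happens: `balance = "paper"` (whole set first — the historical,
optimistic protocol) or `"fold-safe"` (inside each training fold — leak-free).
See the vignette in `vignettes/` for the reasoning behind each design choice.

## Worked example

Using the bundled synthetic fixture (20 proteins, 60 labelled sites):

```r
library(sulfenpred)

fa  <- system.file("extdata", "synthetic_proteins.fasta", package = "sulfenpred")
tab <- system.file("extdata", "synthetic_sites.csv",     package = "sulfenpred")

frags <- extract_fragments(read_fasta(fa), read_site_table(tab))
frags <- frags[frags$label != "unknown", ]   # keep the 60 labelled cysteines
head(frags, 3)
#>   protein_id position                window    label
#> 1 SYNPROT001       12 DPILIGIHNHCVKSWYGRPTT positive
#> 4 SYNPROT001       42 KRCVCGYQKLCCALAWQAQII negative
#> 7 SYNPROT001       67 FHNRATPVFHCVRGCEGMFSC negative

x <- encode_fragments(frags)                 # 60 x 2203 feature matrix
cv <- cross_validate(x, droplevels(frags$label), n_folds = 5, seed = 1)
cv
#> 5-fold cross-validation (balance = paper, seed = 1)
#>   feature blocks: BE, AAindex, KSAAP, AAC, HQI
#>   ACC 98%  SN 95%  SP 100%  MCC 0.95  AUC 1.00

ablation(x, droplevels(frags$label), n_folds = 5, seed = 1)
#>    blocks   acc  sn    sp   mcc   auc
#> 1      BE 100.0 100 100.0 1.000 1.000
#> 2 AAindex  98.8 100  97.5 0.976 1.000
#> 3   KSAAP  87.5  75 100.0 0.777 1.000
#> 4     AAC  88.8  90  87.5 0.781 0.966
#> 5     HQI  96.2  95  97.5 0.931 0.997
#> 6     All  97.5  95 100.0 0.953 1.000
```

The fixture's positive sites carry a strong compositional motif, so the CV
metrics sit near the ceiling; each ablation row cross-validates one feature
block with identical folds, and the `All` row is the full 2,203-feature
model. On real data, expect the `"paper"` balancing mode to report higher
sensitivity than `"fold-safe"` — that gap is replicate leakage, not signal
(see the vignette).

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "sulfenpred", package = "sulfenpred"))')
Rscript "$CLI" simulate --n-pos 20 --n-neg 40 --strength 0.8 --seed 3 \
        --out-fasta sim.fasta --out-sites sim.csv
Rscript "$CLI" evaluate --fasta sim.fasta --sites sim.csv --folds 10 --seed 3
Rscript "$CLI" train    --fasta sim.fasta --sites sim.csv --seed 3 --out model.rds
Rscript "$CLI" predict  --model model.rds --fasta sim.fasta
```

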