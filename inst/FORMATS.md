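# File formats

All files are UTF-8 CSV with a decimal point and no thousands separators;
numeric cells that fail strict parsing (including locale-style decimal
commas) are rejected with their row and column.

## Indicator table (`score --input`)

Header `treatment,<indicator1>,<indicator2>,...`; one row per treatment;
every measurement strictly positive; treatment labels unique.

## Score configuration (`score --config`, JSON or YAML)

```json
{
  "control": "W",
  "cumulative_threshold": 0.85,
  "polarity": {"proline": "positive", "mda": "negative"}
}
```

`polarity` must cover exactly the indicator columns of the table.

## Score report

CSV: `treatment,composite,rank,F_PC1..,U_PC1..` (component scores F and
membership values U for each retained component). JSON summary: `weights`,
`variance_contributions`, `selected_k`, and a configuration echo.

## Feature statistics (`screen-deg`/`screen-dam --input`)

`feature_id[,kind],fold_change[,log2_fc],p_value[,q_value]`. The DEG screen
needs `q_value`, the DAM screen `p_value`. Screen output CSV:
`feature_id,direction` with `direction` in `up`/`down`.

## Pair table (`quadrant --pairs`)

`gene_id,metabolite_id,rho,gene_log2fc,met_log2fc`. Output adds a
`quadrant` column (`1`..`9`, `filtered`, `missing`); the JSON count summary
names the grid convention: gene axis down/unchanged/up left-to-right,
metabolite axis with up on top, so Q3 = both up, Q7 = both down.

## Simulated fixture directory (`simulate --out-dir`)

`indicators.csv`, `score_config.json`, `genes.csv`, `metabolites.csv`
(features x samples, sample columns `C1..Cn,T1..Tn`), `groups.csv`
(sample,group), `truth.csv` (planted pairs with designed quadrant).
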