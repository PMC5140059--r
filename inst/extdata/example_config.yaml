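# Example run configuration for the simulate/infer/evaluate pipeline.
network: enzymatic_network.yaml   # resolve relative to your working directory
time_points: {scheme: uniform, n_points: 13, t_max: 30}
n_cells: 10000
x0: [100, 200, 0, 0]
replicates: 1
capture_p: 1.0          # binomial capture efficiency; 1 = no measurement noise
gradient_method: spline # spline | fds | smooth
orders: "2"             # "2" = means + (co)variances, "1" = means only
bootstrap_B: 200
nlambda: 50
folds: 5
stability_threshold: 0.8
criterion: BIC
seed: 1
outdir: out
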