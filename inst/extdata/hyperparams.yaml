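# Hyperparameter registry: the learning-rate (eta) / regularisation (alpha)
# pairs used for the reference experiments.
spiking_one_sequence:
  alpha: 3.3e-5
  eta: 2.7e-4
spiking_two_sequences:
  alpha: 1.0e-6
  eta: 4.7e-4
writer_dependent:
  alpha: 8.0e-6
  eta: 3.7e-4
ann_sigmoid:
  alpha: 5.0e-6
  eta: 7.0e-2
ann_lenet_relu:
  eta: 1.0e-2
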