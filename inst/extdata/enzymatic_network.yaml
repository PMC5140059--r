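# Classical enzyme-substrate system: the built-in benchmark fixture.
species: [E, S, ES, P]
reactions:
  - {reactants: [E, S], products: [ES], rate: 0.002}
  - {reactants: [ES], products: [E, S], rate: 0.1}
  - {reactants: [ES], products: [E, P], rate: 0.3}
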