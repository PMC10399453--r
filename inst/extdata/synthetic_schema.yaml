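outcome: 'y'
variables:
- name: V001
  role: continuous
- name: V002
  role: categorical
  levels:
  - '1'
  - '2'
  - '3'
  - '4'
- name: V003
  role: continuous
- name: V004
  role: categorical
  levels:
  - '1'
  - '2'
  - '3'
  - '4'
- name: V005
  role: continuous
- name: V006
  role: categorical
  levels:
  - '1'
  - '2'
  - '3'
  - '4'
- name: V007
  role: continuous
- name: V008
  role: categorical
  levels:
  - '1'
  - '2'
  - '3'
  - '4'
- name: 'y'
  role: continuous
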