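miss_triggers:
- miss
- skip
- forget
- forgot
- forgotten
oc_generic:
- birth control
- contraceptive
- minipill
brands_combined:
- yaz
- yasmin
- alesse
- sprintec
- junel
- levora
- estarylla
- seasonique
- lo loestrin
- ortho tri-cyclen
- apri
- aviane
brands_progestin:
- micronor
- camila
- errin
- heather
- nora-be
- jolivette
- norethindrone
- slynd
miscarriage_phrases:
- after miscarriage
- post miscarriage
- i had a miscarriage
ec_phrases:
- plan b
- morning after pill
exclusion_terms:
- law
- laws
- legal
- illegal
- legislation
- ban
- bans
- banned
- debate
- court
- senate
- supreme
- election
- vote
- politics
- protest
- news
celebrity_terms:
- celebrity
- celebrities
- famous
- actress
number_words:
  one: 1.0
  two: 2.0
  three: 3.0
  four: 4.0
  five: 5.0
  six: 6.0
  seven: 7.0
  eight: 8.0
  nine: 9.0
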